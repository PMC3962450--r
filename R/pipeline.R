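# End-to-end two-stream study orchestration: simulate, assign scans to
# streams, fit tensors, extract region means, run the reliability
# analyses, and write a complete, manifest-tracked output bundle.

#' Randomly assign repeat scans to two analysis streams
#'
#' Each subject's two back-to-back scans are split between two independent
#' processing streams by a seeded fair coin, so that acquisition order
#' cannot influence the results. The coin for each subject is derived from
#' the seed and the subject id (not the subject's position), so permuting
#' subject order does not change the assignment.
#'
#' @param subjects Character vector of subject ids (each having exactly 2
#'   scans), or a data.frame with columns `subject_id` and `repeat_index`
#'   which is validated to contain exactly 2 scans per subject.
#' @param seed Integer seed for the assignment coins.
#' @return data.frame with columns `subject_id`, `stream_a_repeat`,
#'   `stream_b_repeat` (each row a permutation of 1:2).
#' @export
assign_streams <- function(subjects, seed) {
  if (is.data.frame(subjects)) {
    counts <- table(subjects$subject_id)
    bad <- names(counts)[counts != 2L]
    if (length(bad))
      stop_data("subjects without exactly 2 scans: ",
                paste(bad, collapse = ", "))
    ids <- names(counts)
  } else {
    ids <- as.character(subjects)
    if (anyDuplicated(ids)) stop_data("duplicated subject ids")
  }
  a <- vapply(ids, function(id) {
    set.seed(derive_seed(seed, "stream", id))
    if (stats::runif(1) < 0.5) 1L else 2L
  }, 0L)
  data.frame(subject_id = ids, stream_a_repeat = unname(a),
             stream_b_repeat = 3L - unname(a), stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Cumulative Huntington's disease burden
#'
#' The standard disease-burden index `age * (CAG - 35.5)`, combining age
#' in years with the CAG trinucleotide repeat length. Values for CAG at or
#' below 35.5 are returned as computed (zero or negative).
#'
#' @param age Age in years (positive).
#' @param cag CAG repeat length.
#' @return Numeric disease-burden score (vectorized).
#' @examples
#' disease_burden(50, 45.5)  # 500
#' @export
disease_burden <- function(age, cag) {
  if (any(age <= 0)) stop_data("age must be positive")
  age * (cag - 35.5)
}

#' Simulate cohort demographic metadata
#'
#' Draws per-subject demographics emulating an early-HD test-retest
#' cohort: control ages ~ N(45.9, 15.7^2) within `[23.4, 67.9]` years, HD
#' ages ~ N(51.0, 7.7^2) within `[42.2, 66.5]`; CAG repeat lengths
#' ~ round(N(43.3, 2.4^2)) within `[39, 46]` (HD only); Total Functional
#' Capacity 13 for controls and round(N(11.5, 1.3^2)) within `[9, 13]` for
#' HD (stage I disease requires TFC >= 11 at entry; the retest sample is
#' reported at assessment). Disease burden is derived via
#' [disease_burden()].
#'
#' @param n_control,n_hd Group sizes.
#' @param seed Integer seed.
#' @return data.frame with columns `subject_id`, `group`, `age`, `cag`,
#'   `tfc`, `disease_burden` (`cag`, `tfc`, `disease_burden` are `NA` for
#'   controls except `tfc = 13`).
#' @export
make_cohort_metadata <- function(n_control, n_hd, seed) {
  rtrunc_norm <- function(n, mean, sd, lo, hi) {
    out <- numeric(n)
    for (i in seq_len(n)) {
      repeat {
        x <- stats::rnorm(1, mean, sd)
        if (x >= lo && x <= hi) break
      }
      out[i] <- x
    }
    out
  }
  set.seed(derive_seed(seed, "metadata"))
  ids <- c(sprintf("ctrl%02d", seq_len(n_control)),
           sprintf("hd%02d", seq_len(n_hd)))
  group <- c(rep("control", n_control), rep("hd", n_hd))
  age <- c(rtrunc_norm(n_control, 45.88, 15.69, 23.44, 67.87),
           rtrunc_norm(n_hd, 50.97, 7.68, 42.19, 66.46))
  cag <- c(rep(NA_real_, n_control),
           pmin(46, pmax(39, round(stats::rnorm(n_hd, 43.3, 2.4)))))
  tfc <- c(rep(13, n_control),
           pmin(13, pmax(9, round(stats::rnorm(n_hd, 11.5, 1.27)))))
  age <- round(age, 2)
  db <- ifelse(is.na(cag), NA_real_, disease_burden(age, cag))
  data.frame(subject_id = ids, group = group, age = age,
             cag = cag, tfc = tfc, disease_burden = round(db, 1),
             stringsAsFactors = FALSE)
}

#' Study configuration
#'
#' Bundles the phantom configuration, the acquisition scheme parameters,
#' the analysis thresholds and the seeds controlling a full two-stream
#' study run. Defaults give the desk-scale study: 22 subjects (12 control,
#' 10 HD), a 20 x 20 x 10 grid, 42 directions at b = 1000 s/mm^2 plus 7
#' b = 0 volumes.
#'
#' @param phantom A [phantom_config()].
#' @param n_directions,n_b0,b Acquisition scheme parameters
#'   (see [default_scheme()]).
#' @param fa_threshold Strict template-FA threshold for atlas regions.
#' @param seed Global simulation seed (overrides `phantom$seed`).
#' @param stream_assignment_seed Seed for the stream-assignment coins.
#' @param t1_exclude Character vector of subject ids excluded from
#'   non-thresholded (T1-segmentation style) regions, emulating subjects
#'   without a structural scan.
#' @return Object of class `study_config`.
#' @export
study_config <- function(phantom = phantom_config(),
                         n_directions = 42L, n_b0 = 7L, b = 1000,
                         fa_threshold = 0.2, seed = 42L,
                         stream_assignment_seed = 1234L,
                         t1_exclude = character(0)) {
  if (!inherits(phantom, "phantom_config"))
    stop_config("phantom must be a phantom_config")
  phantom$seed <- as.integer(seed)
  structure(list(phantom = phantom, n_directions = as.integer(n_directions),
                 n_b0 = as.integer(n_b0), b = b,
                 fa_threshold = fa_threshold, seed = as.integer(seed),
                 stream_assignment_seed = as.integer(stream_assignment_seed),
                 t1_exclude = as.character(t1_exclude)),
            class = "study_config")
}

#' Read and write study configurations as flat key-value text
#'
#' Study-level keys are stored alongside the phantom keys (the phantom
#' block uses the same layout as [write_phantom_config()]).
#'
#' @param config A [study_config()].
#' @param path Text file path.
#' @return `write_study_config()` returns `path` invisibly;
#'   `read_study_config()` returns a [study_config()].
#' @export
write_study_config <- function(config, path) {
  write_phantom_config(config$phantom, path)
  cat(paste0(c(
    paste0("n_directions=", config$n_directions),
    paste0("n_b0=", config$n_b0),
    paste0("b=", fmt_num(config$b)),
    paste0("fa_threshold=", fmt_num(config$fa_threshold)),
    paste0("stream_assignment_seed=", config$stream_assignment_seed),
    paste0("t1_exclude=", paste(config$t1_exclude, collapse = ","))),
    collapse = "\n"), "\n", sep = "", file = path, append = TRUE)
  invisible(path)
}

#' @rdname write_study_config
#' @export
read_study_config <- function(path) {
  phantom <- read_phantom_config(path)
  kv <- parse_kv(path)
  opt <- function(key, default) if (key %in% names(kv)) kv[[key]] else default
  t1x <- opt("t1_exclude", "")
  study_config(
    phantom = phantom,
    n_directions = as.integer(opt("n_directions", 42L)),
    n_b0 = as.integer(opt("n_b0", 7L)),
    b = as.numeric(opt("b", 1000)),
    fa_threshold = as.numeric(opt("fa_threshold", 0.2)),
    seed = phantom$seed,
    stream_assignment_seed = as.integer(opt("stream_assignment_seed", 1234L)),
    t1_exclude = if (nzchar(t1x)) strsplit(t1x, ",")[[1]] else character(0))
}

#' Run the full two-stream test-retest study
#'
#' Executes the complete pipeline: simulate the cohort, randomly assign
#' each subject's two scans to analysis streams A and B, fit the diffusion
#' tensor per voxel in every scan, build per-stream FA templates, extract
#' region means, and compute the reliability tables, summaries, voxelwise
#' ICC maps (all four metrics, per group) and pooled-group Bland-Altman
#' statistics. All outputs are written under `output_dir` and listed in
#' `manifest.tsv` together with the seeds, package version, per-stage wall
#' times and tensor-fit non-convergence counts. Byte-identical TSV outputs
#' are produced for identical seeds.
#'
#' @param config A [study_config()].
#' @param output_dir Output directory (created if needed).
#' @param fit_method Tensor fit passed to [fit_volume()].
#' @return Invisibly, a list with the in-memory tables (`measurements`,
#'   `reliability`, `summary`, `bland_altman`, `metadata`, `streams`), the
#'   voxelwise ICC results, and `manifest`.
#' @export
run_study <- function(config, output_dir,
                      fit_method = c("nlls", "loglinear")) {
  fit_method <- match.arg(fit_method)
  if (!inherits(config, "study_config"))
    stop_config("config must be a study_config")
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  timings <- list()
  run_stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    message(sprintf("[%s] starting (seed %d)", name, config$seed))
    out <- tryCatch(expr, error = function(e) {
      stop(errorCondition(sprintf("stage '%s' failed: %s", name,
                                  conditionMessage(e)),
                          class = c(class(e)[1], "error", "condition")))
    })
    timings[[name]] <<- proc.time()[["elapsed"]] - t0
    out
  }
  files <- character(0)
  declare <- function(...) files <<- c(files, ...)

  scheme <- default_scheme(config$n_directions, config$n_b0, config$b)
  cohort <- run_stage("simulate", {
    ch <- generate_cohort(config$phantom, scheme)
    input_dir <- file.path(output_dir, "input")
    declare(write_cohort(ch, input_dir))
    ch
  })
  meta <- run_stage("metadata", {
    md <- make_cohort_metadata(config$phantom$n_control,
                               config$phantom$n_hd, config$seed)
    declare(write_tsv(md, file.path(output_dir, "participants.tsv")))
    md
  })
  ids <- vapply(cohort$subjects, `[[`, "", "subject_id")
  streams <- run_stage("assign_streams", {
    st <- assign_streams(ids, config$stream_assignment_seed)
    declare(write_tsv(st, file.path(output_dir, "streams.tsv")))
    st
  })

  maps_dir <- file.path(output_dir, "maps")
  dir.create(maps_dir, showWarnings = FALSE)
  n_nonconv <- 0L
  maps <- run_stage("fit", {
    out <- list()
    for (s in cohort$subjects) {
      st <- streams[streams$subject_id == s$subject_id, ]
      for (stream_i in 1:2) {  # 1 = stream A, 2 = stream B
        scan <- if (stream_i == 1L) st$stream_a_repeat else st$stream_b_repeat
        fit <- suppressMessages(
          fit_volume(s$dwi[[scan]], scheme, method = fit_method))
        n_nonconv <- n_nonconv + fit$n_nonconverged
        metrics <- list(FA = fit$fa, MD = fit$md, AD = fit$ad, RD = fit$rd)
        for (metric in METRICS) {
          p <- file.path(maps_dir, sprintf("%s_stream%s_%s.nii.gz",
                                           s$subject_id, c("A", "B")[stream_i],
                                           metric))
          write_nifti(metrics[[metric]], p)
          declare(p)
        }
        out[[length(out) + 1L]] <- list(
          subject_id = s$subject_id, group = s$group,
          repeat_index = stream_i, metrics = metrics)
      }
    }
    message(sprintf("[fit] %d non-converged voxel fits in total", n_nonconv))
    out
  })

  templates <- run_stage("templates", {
    tl <- list(fa_template(maps, 1L), fa_template(maps, 2L))
    for (i in 1:2) {
      p <- file.path(output_dir, sprintf("fa_template_stream%s.nii.gz",
                                         c("A", "B")[i]))
      write_nifti(tl[[i]], p)
      declare(p)
    }
    tl
  })

  measurements <- run_stage("measurements", {
    mt <- build_measurement_table(maps, cohort$labels,
                                  config$phantom$region_spec,
                                  fa_templates = templates,
                                  fa_threshold = config$fa_threshold)
    if (length(config$t1_exclude)) {
      t1_regions <- config$phantom$region_spec$region_name[
        !config$phantom$region_spec$fa_thresholded]
      drop <- mt$subject_id %in% config$t1_exclude & mt$region %in% t1_regions
      mt <- mt[!drop, ]
    }
    declare(write_tsv(mt, file.path(output_dir, "measurements.tsv")))
    mt
  })

  rel <- run_stage("reliability", {
    tab <- reliability_table(measurements)
    declare(write_reliability_tsv(tab,
                                  file.path(output_dir, "reliability.tsv")))
    tab
  })
  summ <- run_stage("summary", {
    sm <- reliability_summary(rel)
    declare(write_tsv(sm, file.path(output_dir, "summary.tsv")))
    sm
  })

  ba <- run_stage("bland_altman", {
    rows <- list(); pair_rows <- list()
    for (region_i in unique(measurements$region))
      for (metric_i in METRICS) {
        ser <- series_from_measurements(measurements, region_i, metric_i)
        res <- bland_altman(ser)
        rows[[length(rows) + 1L]] <- data.frame(
          region = region_i, metric = metric_i, n = res$n,
          mean_diff = res$mean_diff, sd_diff = res$sd_diff,
          loa_low = res$loa_low, loa_high = res$loa_high,
          stringsAsFactors = FALSE)
        pr <- res$pairs
        pr$region <- region_i; pr$metric <- metric_i
        pair_rows[[length(pair_rows) + 1L]] <- pr
      }
    tab <- do.call(rbind, rows)
    declare(write_tsv(tab, file.path(output_dir, "bland_altman.tsv")))
    pairs <- do.call(rbind, pair_rows)[, c("region", "metric", "subject_id",
                                           "mean", "diff")]
    declare(write_tsv(pairs, file.path(output_dir, "bland_altman_pairs.tsv")))
    list(table = tab, pairs = pairs)
  })

  vox <- run_stage("voxelwise", {
    grid <- config$phantom$grid_shape
    mask <- cohort$labels > 0L
    out <- list()
    groups <- vapply(cohort$subjects, `[[`, "", "group")
    for (g in unique(groups)) {
      sel <- which(vapply(maps, function(m) m$group == g &&
                            m$repeat_index == 1L, TRUE))
      selB <- which(vapply(maps, function(m) m$group == g &&
                             m$repeat_index == 2L, TRUE))
      idA <- vapply(maps[sel], `[[`, "", "subject_id")
      idB <- vapply(maps[selB], `[[`, "", "subject_id")
      selB <- selB[match(idA, idB)]
      for (metric in METRICS) {
        stackA <- array(unlist(lapply(maps[sel],
                                      function(m) m$metrics[[metric]])),
                        dim = c(grid, length(sel)))
        stackB <- array(unlist(lapply(maps[selB],
                                      function(m) m$metrics[[metric]])),
                        dim = c(grid, length(selB)))
        res <- suppressMessages(
          voxelwise_icc(stackA, stackB, mask, idA, idA))
        p <- file.path(output_dir, sprintf("icc_%s_%s.nii.gz", metric, g))
        write_nifti(res$icc, p)
        declare(p)
        out[[paste(metric, g, sep = "_")]] <- res
      }
    }
    out
  })

  manifest <- run_stage("manifest", {
    info <- data.frame(
      kind = c("config", "config", "seed", "seed", "version", "version",
               "count",
               rep("timing", length(timings))),
      name = c("n_control", "n_hd", "seed", "stream_assignment_seed",
               "dtiretest", "R", "nonconverged_voxel_fits",
               paste0("stage_", names(timings))),
      value = c(config$phantom$n_control, config$phantom$n_hd,
                config$seed, config$stream_assignment_seed,
                as.character(utils::packageVersion("dtiretest")),
                paste(R.version$major, R.version$minor, sep = "."),
                n_nonconv,
                sprintf("%.2f", unlist(timings))),
      stringsAsFactors = FALSE)
    cfg_path <- file.path(output_dir, "study_config.txt")
    write_study_config(config, cfg_path)
    declare(cfg_path)
    fdf <- data.frame(kind = "file", name = basename(files), value = files,
                      stringsAsFactors = FALSE)
    man <- rbind(info, fdf)
    write_tsv(man, file.path(output_dir, "manifest.tsv"))
    man
  })

  invisible(list(measurements = measurements, reliability = rel,
                 summary = summ, bland_altman = ba, voxelwise = vox,
                 metadata = meta, streams = streams, manifest = manifest,
                 n_nonconverged = n_nonconv, output_dir = output_dir))
}
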