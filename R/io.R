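# File interfaces: NIfTI-1 volumes, FSL gradient tables, label lookup
# tables, truth manifests, and the flat key-value phantom config format.

# 2 mm isotropic RAS+ affine matching the simulated acquisition.
nifti_image <- function(arr, pixdim = c(2, 2, 2)) {
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- c(pixdim, rep(1, max(0, length(dim(arr)) - 3L)))
  RNifti::sform(img) <- structure(
    rbind(cbind(diag(pixdim), c(0, 0, 0)), c(0, 0, 0, 1)), code = 2L)
  img
}

#' Read and write NIfTI-1 volumes
#'
#' Thin wrappers around \pkg{RNifti} fixing the package conventions: voxel
#' arrays in RAS+ orientation with a 2 mm isotropic affine written to the
#' header.
#'
#' @param arr Numeric array (3D or 4D).
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `write_nifti()` returns `path` invisibly; `read_nifti()` returns
#'   a plain numeric array.
#' @export
write_nifti <- function(arr, path) {
  RNifti::writeNifti(nifti_image(arr), path)
  invisible(path)
}

#' @rdname write_nifti
#' @export
read_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  attributes(arr) <- list(dim = dim(arr))
  arr
}

#' Write a simulated cohort to disk
#'
#' Writes every subject's two repeat scans as 4D NIfTI-1 volumes, the
#' shared gradient table in FSL `bvals`/`bvecs` dialect, the integer label
#' volume with its `labels.tsv` lookup (label_id, region_name), the
#' ground-truth manifest `truth.tsv` (subject_id, group, region, true mean
#' FA/MD/AD/RD), and the generating configuration as a flat key-value
#' `config.txt`.
#'
#' @param cohort A `dwi_cohort` from [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, a character vector of the files written.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (s in cohort$subjects) {
    for (rep_i in 1:2) {
      p <- file.path(dir, sprintf("%s_rep%d_dwi.nii.gz", s$subject_id, rep_i))
      write_nifti(s$dwi[[rep_i]], p)
      paths <- c(paths, p)
    }
    p <- file.path(dir, sprintf("%s_tensor_truth.nii.gz", s$subject_id))
    write_nifti(s$tensor_truth, p)
    paths <- c(paths, p)
  }
  write_bvalbvec(cohort$scheme, file.path(dir, "bvals"),
                 file.path(dir, "bvecs"))
  write_nifti(cohort$labels, file.path(dir, "labels.nii.gz"))
  write_tsv(cohort$config$region_spec[, c("label_id", "region_name")],
            file.path(dir, "labels.tsv"))
  tt <- truth_table(cohort)
  write_tsv(tt, file.path(dir, "truth.tsv"))
  write_phantom_config(cohort$config, file.path(dir, "config.txt"))
  invisible(c(paths, file.path(dir, c("bvals", "bvecs", "labels.nii.gz",
                                      "labels.tsv", "truth.tsv",
                                      "config.txt"))))
}

fmt_num <- function(x) paste(format(x, digits = 15, trim = TRUE,
                                    scientific = FALSE), collapse = ",")

#' Read and write phantom configurations as flat key-value text
#'
#' One `key=value` pair per line; vector values are comma-separated and the
#' region specification is flattened to `region.<i>.<field>` keys. The key
#' names match the [phantom_config()] fields.
#'
#' @param config A [phantom_config()].
#' @param path Text file path.
#' @return `write_phantom_config()` returns `path` invisibly;
#'   `read_phantom_config()` returns a [phantom_config()].
#' @export
write_phantom_config <- function(config, path) {
  lines <- c(
    paste0("grid_shape=", fmt_num(config$grid_shape)),
    paste0("n_control=", config$n_control),
    paste0("n_hd=", config$n_hd),
    paste0("between_subject_cv=", fmt_num(config$between_subject_cv)),
    paste0("within_subject_cv=", fmt_num(config$within_subject_cv)),
    paste0("rician_sigma=", fmt_num(config$rician_sigma)),
    paste0("s0=", fmt_num(config$s0)),
    paste0("seed=", config$seed),
    paste0("hd_md_shift=", fmt_num(config$hd_md_shift)),
    paste0("hd_fa_shift=", fmt_num(config$hd_fa_shift)),
    paste0("hd_between_scale=", fmt_num(config$hd_between_scale)),
    paste0("anisotropy_between_cv=", fmt_num(config$anisotropy_between_cv)),
    paste0("anisotropy_within_cv=", fmt_num(config$anisotropy_within_cv)))
  rs <- config$region_spec
  for (i in seq_len(nrow(rs))) {
    pre <- sprintf("region.%d.", i)
    r <- rs[i, ]
    lines <- c(lines,
      paste0(pre, "label_id=", r$label_id),
      paste0(pre, "region_name=", r$region_name),
      paste0(pre, "shape=", r$shape),
      if (r$shape == "sphere")
        paste0(pre, "geometry=", fmt_num(c(r$cx, r$cy, r$cz, r$radius)))
      else
        paste0(pre, "geometry=", fmt_num(c(r$x0, r$x1, r$y0, r$y1, r$z0, r$z1))),
      paste0(pre, "eigenvalues=", fmt_num(c(r$l1, r$l2, r$l3))),
      paste0(pre, "direction=", fmt_num(c(r$dx, r$dy, r$dz))),
      paste0(pre, "fa_thresholded=", r$fa_thresholded))
  }
  writeLines(lines, path)
  invisible(path)
}

parse_kv <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  eq <- regexpr("=", lines, fixed = TRUE)
  if (any(eq < 0)) stop_config("malformed config line: ",
                               lines[which(eq < 0)[1]])
  stats::setNames(trimws(substring(lines, eq + 1L)),
                  trimws(substring(lines, 1L, eq - 1L)))
}

kv_num <- function(kv, key) as.numeric(strsplit(kv[[key]], ",")[[1]])

#' @rdname write_phantom_config
#' @export
read_phantom_config <- function(path) {
  if (!file.exists(path)) stop_config("config file not found: ", path)
  kv <- parse_kv(path)
  need <- c("grid_shape", "n_control", "n_hd", "between_subject_cv",
            "within_subject_cv", "rician_sigma", "s0", "seed")
  miss <- setdiff(need, names(kv))
  if (length(miss)) stop_config("missing config keys: ",
                                paste(miss, collapse = ", "))
  idx <- sort(unique(as.integer(sub("^region\\.(\\d+)\\..*$", "\\1",
                                    grep("^region\\.", names(kv),
                                         value = TRUE)))))
  if (!length(idx)) stop_config("config declares no regions")
  rows <- lapply(idx, function(i) {
    p <- function(f) kv[[sprintf("region.%d.%s", i, f)]]
    shape <- p("shape")
    geom <- as.numeric(strsplit(p("geometry"), ",")[[1]])
    lam <- as.numeric(strsplit(p("eigenvalues"), ",")[[1]])
    dirn <- as.numeric(strsplit(p("direction"), ",")[[1]])
    data.frame(label_id = as.integer(p("label_id")),
               region_name = p("region_name"), shape = shape,
               cx = if (shape == "sphere") geom[1] else NA,
               cy = if (shape == "sphere") geom[2] else NA,
               cz = if (shape == "sphere") geom[3] else NA,
               radius = if (shape == "sphere") geom[4] else NA,
               x0 = if (shape == "box") geom[1] else NA,
               x1 = if (shape == "box") geom[2] else NA,
               y0 = if (shape == "box") geom[3] else NA,
               y1 = if (shape == "box") geom[4] else NA,
               z0 = if (shape == "box") geom[5] else NA,
               z1 = if (shape == "box") geom[6] else NA,
               l1 = lam[1], l2 = lam[2], l3 = lam[3],
               dx = dirn[1], dy = dirn[2], dz = dirn[3],
               fa_thresholded = as.logical(p("fa_thresholded")),
               stringsAsFactors = FALSE)
  })
  phantom_config(
    grid_shape = kv_num(kv, "grid_shape"),
    region_spec = do.call(rbind, rows),
    n_control = as.integer(kv[["n_control"]]),
    n_hd = as.integer(kv[["n_hd"]]),
    between_subject_cv = kv_num(kv, "between_subject_cv"),
    within_subject_cv = kv_num(kv, "within_subject_cv"),
    rician_sigma = kv_num(kv, "rician_sigma"),
    s0 = kv_num(kv, "s0"),
    seed = as.integer(kv[["seed"]]),
    hd_md_shift = if ("hd_md_shift" %in% names(kv))
      kv_num(kv, "hd_md_shift") else 0.10,
    hd_fa_shift = if ("hd_fa_shift" %in% names(kv))
      kv_num(kv, "hd_fa_shift") else 0.10,
    hd_between_scale = if ("hd_between_scale" %in% names(kv))
      kv_num(kv, "hd_between_scale") else 1.5,
    anisotropy_between_cv = if ("anisotropy_between_cv" %in% names(kv))
      kv_num(kv, "anisotropy_between_cv") else NULL,
    anisotropy_within_cv = if ("anisotropy_within_cv" %in% names(kv))
      kv_num(kv, "anisotropy_within_cv") else NULL)
}
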