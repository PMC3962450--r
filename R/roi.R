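# Region-of-interest measurement layer: region means of scalar maps per
# subject, repeat and metric, with optional template-FA thresholding of
# white-matter atlas regions to reduce partial volume effects.

#' Mean of a scalar map over a labelled region
#'
#' Averages map values over the voxels carrying `label_id`, optionally
#' restricted to voxels where a template FA map strictly exceeds
#' `fa_threshold` (the conventional FA > 0.2 partial-volume guard for
#' white-matter atlas regions; note the strict inequality).
#'
#' @param map 3D numeric array (one scalar metric).
#' @param labels Integer 3D array of region labels (0 = background).
#' @param label_id Integer label to average over.
#' @param fa_template Optional 3D FA template array; `NULL` disables
#'   thresholding.
#' @param fa_threshold Strict lower FA bound applied to `fa_template`.
#' @return List with `mean` (the region mean) and `n_voxels` (number of
#'   voxels surviving the threshold).
#' @section Errors: a missing label raises a `dtiretest_label_error`
#'   naming the label; a region where no voxel survives the FA threshold
#'   raises a distinct `dtiretest_empty_region` error.
#' @export
region_mean <- function(map, labels, label_id, fa_template = NULL,
                        fa_threshold = 0.2) {
  if (!identical(dim(map), dim(labels)))
    stop_data("map and label volumes have different shapes")
  sel <- labels == label_id
  if (!any(sel))
    stop(errorCondition(
      sprintf("label %s is not present in the label volume", label_id),
      class = c("dtiretest_label_error", "dtiretest_data_error",
                "error", "condition")))
  if (!is.null(fa_template)) {
    if (!identical(dim(fa_template), dim(map)))
      stop_data("FA template shape does not match the map")
    sel <- sel & (fa_template > fa_threshold)
    if (!any(sel))
      stop(errorCondition(
        sprintf("region with label %s has no voxels with template FA > %g",
                label_id, fa_threshold),
        class = c("dtiretest_empty_region", "dtiretest_data_error",
                  "error", "condition")))
  }
  list(mean = mean(map[sel]), n_voxels = sum(sel))
}

#' Voxelwise mean FA template across subjects
#'
#' The per-stream FA template used for thresholding atlas regions: the
#' voxelwise mean of the subjects' FA maps belonging to one repeat/stream.
#'
#' @param maps List of map entries as consumed by
#'   [build_measurement_table()].
#' @param repeat_index Which repeat/stream (1 or 2) to average.
#' @return 3D array of mean FA.
#' @export
fa_template <- function(maps, repeat_index) {
  sel <- Filter(function(m) m$repeat_index == repeat_index, maps)
  if (!length(sel)) stop_data("no maps with repeat_index ", repeat_index)
  Reduce(`+`, lapply(sel, function(m) m$metrics$FA)) / length(sel)
}

#' Assemble the region-measurement table
#'
#' Computes the complete crossing of subjects x repeats x regions x metrics
#' of region means — the analysis table feeding the reliability statistics.
#' Regions flagged `fa_thresholded` in the region specification are
#' averaged under the per-repeat template FA mask; other (T1-segmentation
#' style) regions are averaged unthresholded.
#'
#' @param maps List of entries, one per (subject, repeat): each a list with
#'   `subject_id`, `group`, `repeat_index` (1 or 2) and `metrics`, a named
#'   list of 3D arrays `FA`, `MD`, `AD`, `RD`.
#' @param labels Integer 3D label array.
#' @param region_spec Region data.frame with `label_id`, `region_name` and
#'   `fa_thresholded` columns (see [default_region_spec()]).
#' @param fa_templates Optional list of two 3D FA template arrays (one per
#'   repeat/stream); computed with [fa_template()] when `NULL` and any
#'   region requests thresholding.
#' @param fa_threshold Strict FA threshold for flagged regions.
#' @return data.frame with columns `subject_id`, `group`, `repeat_index`,
#'   `region`, `metric`, `value`, `n_voxels`, ordered by (subject, repeat,
#'   region, metric).
#' @export
build_measurement_table <- function(maps, labels, region_spec,
                                    fa_templates = NULL,
                                    fa_threshold = 0.2) {
  ids <- vapply(maps, `[[`, "", "subject_id")
  reps <- vapply(maps, function(m) as.integer(m$repeat_index), 0L)
  for (id in unique(ids)) {
    have <- sort(reps[ids == id])
    if (!identical(have, 1:2))
      stop_data("subject ", id, " does not have exactly repeats 1 and 2 ",
                "(found: ", paste(have, collapse = ", "), ")")
  }
  if (is.null(fa_templates) && any(region_spec$fa_thresholded))
    fa_templates <- list(fa_template(maps, 1L), fa_template(maps, 2L))
  ord <- order(ids, reps)
  rows <- vector("list", length(maps) * nrow(region_spec) * length(METRICS))
  k <- 0L
  for (m in maps[ord]) {
    for (i in seq_len(nrow(region_spec))) {
      r <- region_spec[i, ]
      tmpl <- if (isTRUE(r$fa_thresholded))
        fa_templates[[m$repeat_index]] else NULL
      for (metric in METRICS) {
        rm <- region_mean(m$metrics[[metric]], labels, r$label_id,
                          fa_template = tmpl, fa_threshold = fa_threshold)
        k <- k + 1L
        rows[[k]] <- data.frame(
          subject_id = m$subject_id, group = m$group,
          repeat_index = as.integer(m$repeat_index),
          region = r$region_name, metric = metric,
          value = rm$mean, n_voxels = rm$n_voxels,
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows[seq_len(k)])
}
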