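# Aggregation-state scoring of single cells over a recovery time course, and
# sedimentation densitometry fractions.

#' Score a cell for internal (cytosolic) aggregates
#'
#' A cell has internal aggregates iff at least one intensity maximum (via
#' [find_maxima()]) lies in the cell interior, i.e. inside the cell mask
#' eroded by `cortical_band` px, and rises at least `noise_tolerance` counts
#' above the cell's diffuse level (the median intensity over the mask). The
#' amplitude condition keeps the broad maximum of a diffusely fluorescent
#' cell, which is always the image's global maximum somewhere, from being
#' scored as an aggregate. Cortical spots (within the band) never flip the
#' call, and "without aggregates" means strictly zero qualifying interior
#' maxima.
#'
#' @param img [channel_image] or matrix.
#' @param cell_mask logical mask of the cell, nonempty.
#' @param cortical_band width (px) of the cortical rim excluded from the
#'   interior, default 3 (about 0.3 um at 0.1 um/px).
#' @param noise_tolerance passed to [find_maxima()]; choose it above the
#'   cell's diffuse contrast and below the aggregate amplitude.
#' @return `TRUE`/`FALSE` (has internal aggregates), or `NA` with attribute
#'   `flag = "unscorable"` when the cell is too small to have an interior
#'   after erosion.
#' @export
score_cell_aggregation <- function(img, cell_mask, cortical_band = 3,
                                   noise_tolerance = NULL) {
  if (!any(cell_mask)) stop("score_cell_aggregation: empty cell mask")
  interior <- .erode_box(cell_mask, as.integer(cortical_band))
  if (!any(interior)) {
    out <- NA
    attr(out, "flag") <- "unscorable"
    return(out)
  }
  mx <- find_maxima(img, noise_tolerance)
  if (nrow(mx$points) == 0) return(FALSE)
  diffuse <- stats::median(.as_pixels(img)[cell_mask])
  inside <- interior[cbind(mx$points$y + 1L, mx$points$x + 1L)]
  any(inside & mx$points$value >= diffuse + mx$noise_tolerance)
}

#' Aggregation time course: percent of cells without internal aggregates
#'
#' @param scores named list, one element per time point, each a logical
#'   vector of per-cell [score_cell_aggregation()] calls (`NA` = unscorable,
#'   dropped from the denominator).
#' @param timepoints numeric time points in minutes; defaults to the list
#'   names coerced to numeric.
#' @return data frame with `timepoint_min`, `n_cells`,
#'   `n_without_aggregates`, `percent_without`.
#' @export
aggregation_timecourse <- function(scores, timepoints = NULL) {
  if (is.null(timepoints)) timepoints <- as.numeric(names(scores))
  if (length(timepoints) != length(scores) || any(is.na(timepoints)))
    stop("aggregation_timecourse: one numeric timepoint per score vector required")
  rows <- lapply(seq_along(scores), function(i) {
    s <- scores[[i]][!is.na(scores[[i]])]
    data.frame(timepoint_min = timepoints[i], n_cells = length(s),
               n_without_aggregates = sum(!s),
               percent_without = 100 * mean(!s))
  })
  do.call(rbind, rows)
}

#' Pellet and supernatant fractions from a densitometry table
#'
#' For each row, `pellet_fraction = P / (P + S)` and
#' `supernatant_fraction = S / (P + S)` (they sum to 1 exactly); per-condition
#' (temperature) means and SDs are also reported, as in replicate
#' sedimentation experiments.
#'
#' @param table data frame with columns `sample_id`, `temperature_C`,
#'   `pellet`, `supernatant` (e.g. from [generate_densitometry()] or
#'   [read_densitometry()]). Intensities must be non-negative with
#'   `P + S > 0` per row.
#' @return list of class `sedimentation_result`: `rows` (per-sample
#'   fractions) and `summary` (per-temperature mean and SD of the pellet
#'   fraction, with `n`).
#' @export
sedimentation_fractions <- function(table) {
  need <- c("sample_id", "temperature_C", "pellet", "supernatant")
  if (!all(need %in% names(table)))
    stop("sedimentation_fractions: table needs columns ",
         paste(need, collapse = ", "))
  if (any(table$pellet < 0 | table$supernatant < 0))
    stop("sedimentation_fractions: negative intensities")
  tot <- table$pellet + table$supernatant
  if (any(tot <= 0))
    stop("sedimentation_fractions: pellet + supernatant must be > 0 per row")
  rows <- data.frame(sample_id = table$sample_id,
                     temperature_C = table$temperature_C,
                     pellet_fraction = table$pellet / tot,
                     supernatant_fraction = table$supernatant / tot)
  agg <- split(rows$pellet_fraction, rows$temperature_C)
  summary <- data.frame(
    temperature_C = as.numeric(names(agg)),
    mean_pellet_fraction = vapply(agg, mean, 0),
    sd_pellet_fraction = vapply(agg, function(v)
      if (length(v) > 1) stats::sd(v) else 0, 0),
    n = vapply(agg, length, 0L))
  rownames(summary) <- NULL
  structure(list(rows = rows, summary = summary),
            class = "sedimentation_result")
}

#' @export
print.sedimentation_result <- function(x, ...) {
  cat("<sedimentation_result>\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Read a densitometry CSV
#'
#' Expects the header `sample_id,temperature_C,pellet,supernatant`.
#'
#' @param path CSV file path.
#' @return data frame suitable for [sedimentation_fractions()].
#' @export
read_densitometry <- function(path) {
  if (!file.exists(path)) stop("read_densitometry: file not found: ", path)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
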