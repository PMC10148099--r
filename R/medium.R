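#' Net metabolite appearance rate in conditioned medium
#'
#' Net appearance per hour over the conditioning period:
#' `(conditioned - unconditioned) / duration_h`. Positive values are net
#' release into the medium by the cells; negative values net consumption.
#'
#' @param conditioned_conc concentration after conditioning, uM.
#' @param unconditioned_conc baseline medium concentration, uM.
#' @param duration_h conditioning period in hours (default 24).
#' @return Numeric rate(s) in uM/h (vectorized).
#' @export
#' @examples
#' net_rate(48, 24)          # +1 uM/h released
#' net_rate(0, 24, 24)       # -1 uM/h consumed
net_rate <- function(conditioned_conc, unconditioned_conc, duration_h = 24) {
  if (any(duration_h <= 0)) stop("duration_h must be positive")
  if (any(conditioned_conc < 0) || any(unconditioned_conc < 0)) {
    stop("concentrations must be nonnegative")
  }
  (conditioned_conc - unconditioned_conc) / duration_h
}

#' Summarize net medium rates per metabolite and group
#'
#' Computes each replicate's net rate via [net_rate()], then the mean and
#' standard error (sample SD / sqrt(n)) per (metabolite, group) cell.
#'
#' @param measurements data.frame with columns `metabolite`, `group`,
#'   `replicate`, `conditioned_conc_uM`, `unconditioned_conc_uM` and
#'   optionally `duration_h` (default 24), as produced by
#'   [make_medium_table()] or [read_medium_csv()].
#' @return data.frame with columns `metabolite`, `group`, `n`,
#'   `mean_rate_uM_h`, `sem_rate_uM_h` (`NA` when n = 1), ordered by
#'   metabolite then group.
#' @export
summarize_rates <- function(measurements) {
  req <- c("metabolite", "group", "replicate", "conditioned_conc_uM",
           "unconditioned_conc_uM")
  if (!is.data.frame(measurements) || !nrow(measurements)) {
    stop("measurements must be a non-empty data.frame")
  }
  missing_cols <- setdiff(req, names(measurements))
  if (length(missing_cols)) {
    stop("missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (is.null(measurements$duration_h)) measurements$duration_h <- 24
  rates <- net_rate(measurements$conditioned_conc_uM,
                    measurements$unconditioned_conc_uM,
                    measurements$duration_h)
  key <- interaction(measurements$metabolite, measurements$group,
                     drop = TRUE, sep = "\r")
  sp <- split(rates, key)
  parts <- strsplit(names(sp), "\r", fixed = TRUE)
  out <- data.frame(
    metabolite = vapply(parts, `[`, "", 1),
    group = vapply(parts, `[`, "", 2),
    n = vapply(sp, length, 1L),
    mean_rate_uM_h = vapply(sp, mean, 1),
    sem_rate_uM_h = vapply(sp, function(r) {
      if (length(r) < 2) NA_real_ else stats::sd(r) / sqrt(length(r))
    }, 1),
    stringsAsFactors = FALSE, row.names = NULL)
  out[order(out$metabolite, out$group), , drop = FALSE]
}

#' Read medium concentration measurements from CSV
#'
#' Expects a header
#' `metabolite,group,replicate,conditioned_conc_uM,unconditioned_conc_uM,duration_h`
#' (`duration_h` optional, default 24).
#'
#' @param path CSV file path.
#' @return data.frame of measurements.
#' @export
read_medium_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("metabolite", "group", "replicate", "conditioned_conc_uM",
           "unconditioned_conc_uM")
  missing_cols <- setdiff(req, names(x))
  if (length(missing_cols)) {
    stop("CSV lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (is.null(x$duration_h)) x$duration_h <- 24
  x
}

#' Write a rate table as TSV
#'
#' @param rates data.frame from [summarize_rates()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_rate_table <- function(rates, path) {
  utils::write.table(rates, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
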