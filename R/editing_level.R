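#' Wilson score interval for a binomial proportion
#'
#' Closed-form Wilson interval (no continuity correction).
#'
#' @param x number of successes.
#' @param n number of trials (> 0).
#' @param conf confidence level.
#' @return numeric vector `c(low, high)` (matrix for vector input).
#' @export
wilson_interval <- function(x, n, conf = 0.95) {
  stopifnot(all(n > 0), all(x >= 0), all(x <= n))
  z <- qnorm(1 - (1 - conf) / 2)
  p <- x / n
  denom <- 1 + z^2 / n
  center <- (p + z^2 / (2 * n)) / denom
  half <- (z / denom) * sqrt(p * (1 - p) / n + z^2 / (4 * n^2))
  out <- cbind(low = pmax(0, center - half), high = pmin(1, center + half))
  if (length(x) == 1L) out[1L, ] else out
}

.level_measurement <- function(site, sample_id, method, numerator,
                               denominator, ci = c(NA_real_, NA_real_)) {
  data.frame(site = site, sample_id = sample_id, method = method,
             numerator = numerator, denominator = denominator,
             level = numerator / denominator,
             ci_low = ci[[1L]], ci_high = ci[[2L]],
             stringsAsFactors = FALSE)
}

#' Editing level from chromatogram peak heights
#'
#' The editing level of a site in a sample is the ratio of the T peak to
#' the sum of the C and T peak heights in the cDNA sequencing
#' chromatogram: `h_T / (h_T + h_C)`. Peak heights are taken as provided;
#' no interval is attached (a single trace carries no sampling model).
#'
#' @param h_T,h_C non-negative T and C peak heights (not both zero).
#' @param site site label (e.g. `"matK:701"`).
#' @param sample_id sample/cultivar label.
#' @return one-row measurement data frame with `level` in \[0, 1\].
#' @export
#' @examples
#' level_from_peaks(840, 0)$level   # complete editing
#' level_from_peaks(30, 70)$level   # 30 % edited
level_from_peaks <- function(h_T, h_C, site = NA_character_,
                             sample_id = NA_character_) {
  stopifnot(length(h_T) == 1L, length(h_C) == 1L)
  if (h_T < 0 || h_C < 0) stop("peak heights must be non-negative")
  if (h_T + h_C == 0) {
    stop("undefined editing level: both C and T peaks are zero")
  }
  .level_measurement(site, sample_id, "peaks", h_T, h_T + h_C)
}

#' Editing level from RNA read counts
#'
#' Read-count analogue of the peak ratio: `n_T / (n_T + n_C)` with a
#' Wilson 95 % confidence interval.
#'
#' @param n_T,n_C non-negative integer T and C read counts (total >= 1).
#' @param site,sample_id labels.
#' @param conf confidence level for the Wilson interval.
#' @return one-row measurement data frame with `level`, `ci_low`,
#'   `ci_high`.
#' @export
level_from_counts <- function(n_T, n_C, site = NA_character_,
                              sample_id = NA_character_, conf = 0.95) {
  stopifnot(length(n_T) == 1L, length(n_C) == 1L)
  if (n_T < 0 || n_C < 0 || n_T != floor(n_T) || n_C != floor(n_C)) {
    stop("read counts must be non-negative integers")
  }
  if (n_T + n_C < 1) stop("undefined editing level: zero total reads")
  ci <- wilson_interval(n_T, n_T + n_C, conf)
  .level_measurement(site, sample_id, "reads", n_T, n_T + n_C, ci)
}

#' Tabulate editing-level measurements as a site-by-sample matrix
#'
#' @param measurements data frame of rows produced by
#'   [level_from_peaks()] / [level_from_counts()] (rbind-ed).
#' @return numeric matrix, sites as rows and samples as columns, `NA`
#'   for missing cells.
#' @export
level_table <- function(measurements) {
  stopifnot(is.data.frame(measurements),
            all(c("site", "sample_id", "method", "level") %in%
                  names(measurements)))
  key <- paste(measurements$site, measurements$sample_id,
               measurements$method, sep = "\r")
  if (anyDuplicated(key)) {
    d <- measurements[duplicated(key), , drop = FALSE][1L, ]
    stop("duplicate measurement for site '", d$site, "', sample '",
         d$sample_id, "', method '", d$method, "'")
  }
  sites <- unique(measurements$site)
  samples <- unique(measurements$sample_id)
  m <- matrix(NA_real_, nrow = length(sites), ncol = length(samples),
              dimnames = list(sites, samples))
  m[cbind(match(measurements$site, sites),
          match(measurements$sample_id, samples))] <- measurements$level
  m
}

#' Qualitative editing-level bins
#'
#' Convenience labels mirroring narrative descriptions of chromatogram
#' levels; never used in computation.
#'
#' @param level numeric vector in \[0, 1\].
#' @return factor with levels `<10%`, `~30%`, `~50%`, `>80%`, `~100%`.
#' @export
level_bins <- function(level) {
  stopifnot(all(level >= 0 & level <= 1, na.rm = TRUE))
  cut(level, breaks = c(-Inf, 0.10, 0.40, 0.65, 0.90, Inf),
      labels = c("<10%", "~30%", "~50%", ">80%", "~100%"),
      right = FALSE)
}

#' Read a chromatogram peak-height table and compute editing levels
#'
#' Peaks TSV columns: `site`, `sample`, `h_A`, `h_C`, `h_G`, `h_T`.
#'
#' @param path TSV path.
#' @return measurement data frame (one row per site/sample).
#' @export
read_peaks <- function(path) {
  if (!file.exists(path)) stop("peak table not found: ", path)
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("site", "sample", "h_C", "h_T")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("peak table '", path, "' lacks column(s): ",
                         paste(miss, collapse = ", "))
  do.call(rbind, lapply(seq_len(nrow(df)), function(i) {
    level_from_peaks(df$h_T[i], df$h_C[i], site = df$site[i],
                     sample_id = df$sample[i])
  }))
}
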