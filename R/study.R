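#' Summarize HDR/NHEJ replicate frequencies for one condition
#'
#' Computes mean and SEM of the per-replicate HDR and NHEJ allelic
#' frequencies, a two-tailed two-sample Student's t-test (equal variance)
#' between the HDR and NHEJ replicate sets, the HDR:NHEJ ratio of means,
#' and the five-tier classification of [tier_classify()]. With fewer than
#' two replicates the summary is returned without a p-value.
#'
#' @param hdr_freqs,nhej_freqs Equal-length numeric vectors of
#'   per-replicate frequencies in percent.
#' @param condition Optional label (or named list of labels) identifying
#'   the condition (locus, nuclease, donor strand, cell type, ...).
#' @return A one-row data frame with columns `condition`, `n`, `mean_hdr`,
#'   `sem_hdr`, `mean_nhej`, `sem_nhej`, `p_value`, `ratio`, `tier`.
#' @export
summarize_condition <- function(hdr_freqs, nhej_freqs, condition = NA) {
  if (!is.numeric(hdr_freqs) || !is.numeric(nhej_freqs) ||
      length(hdr_freqs) != length(nhej_freqs))
    stop("hdr_freqs and nhej_freqs must be numeric vectors of equal length")
  if (length(hdr_freqs) < 1L) stop("at least one replicate required")
  if (any(!is.finite(c(hdr_freqs, nhej_freqs))) ||
      any(c(hdr_freqs, nhej_freqs) < 0))
    stop("frequencies must be finite and >= 0")
  n <- length(hdr_freqs)
  sem <- function(x) if (n >= 2L) stats::sd(x) / sqrt(n) else NA_real_
  mh <- mean(hdr_freqs); mn <- mean(nhej_freqs)
  p <- NA_real_
  if (n >= 2L) {
    if (stats::sd(hdr_freqs) == 0 && stats::sd(nhej_freqs) == 0) {
      # degenerate constant replicates: identical sets are indistinguishable
      p <- if (mh == mn) 1 else 0
    } else {
      p <- stats::t.test(hdr_freqs, nhej_freqs, var.equal = TRUE,
                         alternative = "two.sided")$p.value
    }
  }
  if (is.list(condition)) condition <- paste(unlist(condition),
                                             collapse = " / ")
  data.frame(condition = as.character(condition), n = n,
             mean_hdr = mh, sem_hdr = sem(hdr_freqs),
             mean_nhej = mn, sem_nhej = sem(nhej_freqs),
             p_value = p,
             ratio = if (mn > 0) mh / mn else if (mh > 0) Inf else NA_real_,
             tier = tier_classify(mh, mn),
             stringsAsFactors = FALSE)
}

#' Five-tier classification of an editing condition
#'
#' Orders conditions from best to worst for precise editing:
#' \enumerate{
#'   \item >0.1% HDR and at least as much HDR as NHEJ;
#'   \item <=0.1% HDR and at least as much HDR as NHEJ;
#'   \item NHEJ above HDR but within 2-fold (`2*HDR >= NHEJ > HDR`);
#'   \item >0.1% HDR but NHEJ more than twice HDR;
#'   \item <=0.1% HDR and NHEJ more than twice HDR.
#' }
#' Boundary ties (HDR equal to NHEJ, to 0.1%, or NHEJ equal to 2x HDR) go
#' to the better tier; the 2-fold band of tier 3 ignores the 0.1%
#' threshold.
#'
#' @param mean_hdr,mean_nhej Mean frequencies in percent (`>= 0`);
#'   vectorized.
#' @param hdr_threshold The "appreciable HDR" threshold in percent
#'   (default 0.1).
#' @return Integer tier(s) in 1..5.
#' @examples
#' tier_classify(0.2, 0.1)   # 1
#' tier_classify(0.6, 0.8)   # 3
#' tier_classify(0.05, 0.2)  # 5
#' @export
tier_classify <- function(mean_hdr, mean_nhej, hdr_threshold = 0.1) {
  if (length(mean_hdr) != length(mean_nhej))
    stop("mean_hdr and mean_nhej must have equal length")
  if (any(!is.finite(c(mean_hdr, mean_nhej))) ||
      any(c(mean_hdr, mean_nhej) < 0))
    stop("frequencies must be finite and >= 0")
  ifelse(mean_hdr >= mean_nhej,
         ifelse(mean_hdr > hdr_threshold, 1L, 2L),
         ifelse(2 * mean_hdr >= mean_nhej, 3L,
                ifelse(mean_hdr > hdr_threshold, 4L, 5L)))
}

#' Squared Pearson correlation between HDR and NHEJ frequencies
#'
#' Zero-valued observations are included (not filtered), matching how the
#' overall HDR-vs-NHEJ relationship is assessed across editing conditions.
#' If either vector is constant the correlation is undefined; 0 is
#' returned with attribute `degenerate = TRUE` and a warning.
#'
#' @param hdr_values,nhej_values Equal-length numeric vectors (`n >= 3`).
#' @return The squared Pearson correlation (R^2) of the simple linear fit.
#' @export
correlation_r2 <- function(hdr_values, nhej_values) {
  if (!is.numeric(hdr_values) || !is.numeric(nhej_values) ||
      length(hdr_values) != length(nhej_values))
    stop("inputs must be numeric vectors of equal length")
  if (length(hdr_values) < 3L) stop("need at least 3 points")
  if (any(!is.finite(c(hdr_values, nhej_values))))
    stop("inputs must be finite")
  if (stats::sd(hdr_values) == 0 || stats::sd(nhej_values) == 0) {
    warning("degenerate input: one variable is constant; R^2 undefined, ",
            "returning 0")
    return(structure(0, degenerate = TRUE))
  }
  stats::cor(hdr_values, nhej_values)^2
}

#' Summarize a tidy multi-condition replicate table
#'
#' @param data A data frame (or CSV path) with numeric columns `hdr` and
#'   `nhej` (per-replicate frequencies in percent) and any number of
#'   condition-identifier columns; rows sharing identifier values are
#'   replicates of one condition.
#' @return A data frame with one row per condition (columns as in
#'   [summarize_condition()], prefixed by the identifier columns), in
#'   first-appearance order.
#' @seealso [tier_matrix()]
#' @export
summarize_study <- function(data) {
  if (is.character(data)) data <- utils::read.csv(data,
                                                  stringsAsFactors = FALSE)
  if (!is.data.frame(data) || !all(c("hdr", "nhej") %in% names(data)))
    stop("data must have columns 'hdr' and 'nhej'")
  id_cols <- setdiff(names(data), c("hdr", "nhej"))
  if (length(id_cols) == 0L) {
    data$condition <- "all"
    id_cols <- "condition"
  }
  key <- do.call(paste, c(data[id_cols], sep = "\r"))
  out <- lapply(unique(key), function(k) {
    rows <- data[key == k, , drop = FALSE]
    cbind(rows[1L, id_cols, drop = FALSE],
          summarize_condition(rows$hdr, rows$nhej,
                              condition = paste(rows[1L, id_cols],
                                                collapse = " / ")),
          row.names = NULL)
  })
  do.call(rbind, out)
}

#' Tier heat-map table from a study summary
#'
#' Reshapes a [summarize_study()] result into a wide matrix of tiers with
#' one identifier as rows and another as columns (the tabular form of a
#' condition heat map).
#'
#' @param summary A data frame from [summarize_study()].
#' @param rows,cols Names of identifier columns to use as rows/columns.
#' @return A data frame of tiers (NA where a combination was not tested).
#' @export
tier_matrix <- function(summary, rows, cols) {
  stopifnot(is.data.frame(summary),
            all(c(rows, cols, "tier") %in% names(summary)))
  rv <- unique(summary[[rows]])
  cv <- unique(summary[[cols]])
  m <- matrix(NA_integer_, length(rv), length(cv),
              dimnames = list(rv, cv))
  for (i in seq_len(nrow(summary)))
    m[as.character(summary[[rows]][i]),
      as.character(summary[[cols]][i])] <- summary$tier[i]
  as.data.frame(m)
}
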