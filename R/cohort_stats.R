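#' Cohort statistics parameters
#'
#' @param bias_low NHEJ/MMEJ ratio below which a guide is MMEJ-biased
#'   (default 0.5).
#' @param bias_high Ratio above which a guide is NHEJ-biased (default 2);
#'   ratios in `[bias_low, bias_high]` are balanced (boundaries inclusive
#'   in the balanced class).
#' @param eff_threshold Editing-efficiency threshold (percent) splitting
#'   guides into low (`E < threshold`, strict) and high (`E >= threshold`)
#'   strata; default 66.7.
#' @return A list of class `StatsParams`.
#' @export
stats_params <- function(bias_low = 0.5, bias_high = 2, eff_threshold = 66.7) {
  if (!(bias_low > 0 && bias_low < bias_high)) {
    stop("need 0 < bias_low < bias_high", call. = FALSE)
  }
  structure(list(bias_low = bias_low, bias_high = bias_high,
                 eff_threshold = eff_threshold),
            class = "StatsParams")
}

.bias_class <- function(ratio, params) {
  if (is.na(ratio)) return("undefined")
  if (ratio < params$bias_low) return("MMEJ-biased")
  if (ratio <= params$bias_high) return("balanced")
  "NHEJ-biased"
}

#' Summarize the embryos of one guide
#'
#' Per-category frequencies are averaged over embryos and the NHEJ/MMEJ
#' ratio is taken on the per-guide means, `R = mean(f_NHEJ) / mean(f_MMEJ)`
#' — not the mean of per-embryo ratios, which would blow up whenever one
#' embryo has no MMEJ mass. `R = Inf` (NHEJ-biased) when the MMEJ mean is
#' zero with positive NHEJ mean; the class is `undefined` when both means
#' are zero.
#'
#' @param profiles [embryo_profiles()] rows for a single guide.
#' @param params [stats_params()].
#' @return One-row data frame: `guide_id`, `n_embryos`, `mean_f_nhej`,
#'   `mean_f_mmej`, `mean_f_hdr`, `mean_f_unedited`, `mean_efficiency`,
#'   `ratio` (full precision), `bias_class`.
#' @export
summarize_guide <- function(profiles, params = stats_params()) {
  if (is.null(nrow(profiles)) || nrow(profiles) == 0L) {
    stop("empty profile list", call. = FALSE)
  }
  if (length(unique(profiles$guide_id)) != 1L) {
    stop("profiles span more than one guide; use summarize_guides()", call. = FALSE)
  }
  mn <- mean(profiles$f_nhej); mm <- mean(profiles$f_mmej)
  ratio <- if (mm > 0) mn / mm else if (mn > 0) Inf else NA_real_
  data.frame(guide_id = profiles$guide_id[1], n_embryos = nrow(profiles),
             mean_f_nhej = mn, mean_f_mmej = mm,
             mean_f_hdr = mean(profiles$f_hdr),
             mean_f_unedited = mean(profiles$f_unedited),
             mean_efficiency = mean(profiles$efficiency),
             ratio = ratio, bias_class = .bias_class(ratio, params),
             stringsAsFactors = FALSE)
}

#' @rdname summarize_guide
#' @param profiles For `summarize_guides()`, profiles spanning any number
#'   of guides; one summary row is produced per guide.
#' @export
summarize_guides <- function(profiles, params = stats_params()) {
  out <- do.call(rbind, lapply(split(profiles, profiles$guide_id),
                               summarize_guide, params = params))
  rownames(out) <- NULL
  out
}

#' Census of repair-bias classes
#'
#' Counts guides per bias class and reports proportions (percent, 2
#' decimals) over the classified guides; `undefined` guides are listed but
#' excluded from the denominator.
#'
#' @param summaries Data frame with a `bias_class` column (from
#'   [summarize_guides()]), or a character vector of classes.
#' @return Data frame `bias_class`, `n`, `pct` with attribute
#'   `n_classified` (the denominator).
#' @export
bias_census <- function(summaries) {
  classes <- if (is.data.frame(summaries)) summaries$bias_class else as.character(summaries)
  if (length(classes) == 0L || all(classes == "undefined")) {
    stop("no summaries with a defined bias class", call. = FALSE)
  }
  lev <- c("MMEJ-biased", "balanced", "NHEJ-biased", "undefined")
  n <- vapply(lev, function(l) sum(classes == l), integer(1))
  denom <- sum(n[lev != "undefined"])
  pct <- ifelse(lev == "undefined", NA_real_, round(100 * n / denom, 2))
  out <- data.frame(bias_class = lev, n = as.integer(n), pct = pct,
                    stringsAsFactors = FALSE)
  out <- out[out$n > 0L | out$bias_class != "undefined", ]
  rownames(out) <- NULL
  attr(out, "n_classified") <- denom
  out
}

#' Stratify guides by editing efficiency
#'
#' Splits guide summaries at `eff_threshold` (low: `E < t`, high:
#' `E >= t`) and reports the proportion of MMEJ-biased guides within each
#' stratum (percent, 2 decimals). The two strata always partition the
#' cohort.
#'
#' @param summaries Output of [summarize_guides()].
#' @param params [stats_params()].
#' @return Data frame `stratum`, `n_guides`, `n_mmej_biased`,
#'   `pct_mmej_biased`.
#' @export
stratify_by_efficiency <- function(summaries, params = stats_params()) {
  t <- params$eff_threshold
  low <- summaries$mean_efficiency < t
  row <- function(name, sel) {
    n <- sum(sel)
    k <- sum(sel & summaries$bias_class == "MMEJ-biased")
    data.frame(stratum = name, n_guides = n, n_mmej_biased = k,
               pct_mmej_biased = if (n > 0) round(100 * k / n, 2) else NA_real_,
               stringsAsFactors = FALSE)
  }
  out <- rbind(row(sprintf("E < %.4g", t), low),
               row(sprintf("E >= %.4g", t), !low))
  rownames(out) <- NULL
  out
}

#' Positive rate of a genotyping trial
#'
#' @param positives Number of positive animals/embryos.
#' @param total Number genotyped (must be positive). Both arguments
#'   vectorize.
#' @return Percent positive, rounded to 2 decimals.
#' @examples
#' positive_rate(6, 11)   # 54.55
#' @export
positive_rate <- function(positives, total) {
  if (any(total <= 0)) stop("total must be positive", call. = FALSE)
  if (any(positives < 0 | positives > total)) {
    stop("need 0 <= positives <= total", call. = FALSE)
  }
  round(100 * positives / total, 2)
}

#' Knock-in efficiency fold change over paired trials
#'
#' For each locus the baseline-arm replicates define a baseline mean
#' efficiency; every treated-arm replicate at that locus contributes a
#' fold `efficiency / baseline_mean`. The overall fold is the unweighted
#' mean over treated replicates. Loci whose baseline mean is zero cannot
#' be normalized and are excluded (and reported).
#'
#' @param trials Data frame with columns `locus_id`, `arm` and
#'   `efficiency` (percent); `arm` takes the values of `baseline_arm` and
#'   `treated_arm`.
#' @param baseline_arm,treated_arm Arm labels (defaults `"baseline"`,
#'   `"treated"`).
#' @return List with `folds` (one row per treated replicate: `locus_id`,
#'   `efficiency`, `baseline_mean`, `fold`), `overall_fold`, and
#'   `excluded_loci`.
#' @export
hdr_fold_change <- function(trials, baseline_arm = "baseline",
                            treated_arm = "treated") {
  need <- c("locus_id", "arm", "efficiency")
  if (!all(need %in% names(trials))) {
    stop("trials require columns: ", paste(need, collapse = ", "), call. = FALSE)
  }
  base <- trials[trials$arm == baseline_arm, , drop = FALSE]
  trt <- trials[trials$arm == treated_arm, , drop = FALSE]
  bm <- tapply(base$efficiency, base$locus_id, mean)
  trt$baseline_mean <- as.numeric(bm[trt$locus_id])
  bad <- is.na(trt$baseline_mean) | trt$baseline_mean <= 0
  excluded <- sort(unique(trt$locus_id[bad]))
  trt <- trt[!bad, , drop = FALSE]
  if (nrow(trt) == 0L) stop("no valid baseline/treated pairs", call. = FALSE)
  trt$fold <- trt$efficiency / trt$baseline_mean
  rownames(trt) <- NULL
  list(folds = trt[, c("locus_id", "efficiency", "baseline_mean", "fold")],
       overall_fold = mean(trt$fold),
       excluded_loci = as.character(excluded))
}
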