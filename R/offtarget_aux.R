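#' Consensus variants across exactly three callers
#'
#' A variant is accepted when its key `(chromosome, position, ref, alt)`
#' is reported by all three callers — the intersection rule used for
#' trusting whole-genome off-target calls. Duplicate records within a
#' caller are ignored; input order is irrelevant.
#'
#' @param variants Data frame with columns `chrom`, `pos` (1-based),
#'   `ref`, `alt`, `caller`.
#' @return Data frame of consensus variants (`chrom`, `pos`, `ref`,
#'   `alt`), sorted by chromosome and position.
#' @export
consensus_variants <- function(variants) {
  need <- c("chrom", "pos", "ref", "alt", "caller")
  if (!all(need %in% names(variants))) {
    stop("variant table requires columns: ", paste(need, collapse = ", "), call. = FALSE)
  }
  callers <- unique(variants$caller)
  if (length(callers) != 3L) {
    stop("consensus undefined: need records from exactly three callers", call. = FALSE)
  }
  key <- function(df) unique(paste(df$chrom, df$pos, df$ref, df$alt, sep = "\r"))
  keys <- Reduce(intersect, lapply(split(variants, variants$caller), key))
  if (length(keys) == 0L) {
    return(data.frame(chrom = character(0), pos = integer(0),
                      ref = character(0), alt = character(0),
                      stringsAsFactors = FALSE))
  }
  parts <- do.call(rbind, strsplit(keys, "\r", fixed = TRUE))
  out <- data.frame(chrom = parts[, 1], pos = as.integer(parts[, 2]),
                    ref = parts[, 3], alt = parts[, 4],
                    stringsAsFactors = FALSE)
  out <- out[order(out$chrom, out$pos, out$ref, out$alt), ]
  rownames(out) <- NULL
  out
}

#' Read one caller's variants from a VCF
#'
#' Minimal reader: only CHROM/POS/REF/ALT are used, tagged with the
#' caller id for [consensus_variants()].
#'
#' @param path Path to an (uncompressed or bgzipped) VCF.
#' @param caller Caller id string.
#' @return Data frame `chrom`, `pos`, `ref`, `alt`, `caller`.
#' @export
read_caller_vcf <- function(path, caller) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  data.frame(chrom = fix[, "CHROM"], pos = as.integer(fix[, "POS"]),
             ref = fix[, "REF"], alt = fix[, "ALT"], caller = caller,
             stringsAsFactors = FALSE)
}

#' Read a chimeric-read table
#'
#' Tab-delimited with header `read_id`, `chrom`, `pos`, `orientation`,
#' `donor_element`, `donor_pos`: one split read per row, aligned partly to
#' the reference genome and partly to the donor construct.
#'
#' @param path Path to the table.
#' @return Data frame with those columns.
#' @export
read_chimeric_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("read_id", "chrom", "pos", "donor_element")
  if (!all(need %in% names(tab))) {
    stop("chimeric-read table requires columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  tab
}

#' Call donor-integration breakpoints from chimeric reads
#'
#' Genome-side positions are clustered per chromosome by single linkage:
#' sorted positions belong to one breakpoint while consecutive gaps stay
#' within `window`. Each cluster's support is its read count; a cluster
#' passes a threshold when `support >= threshold` (inclusive). By default
#' both stated thresholds, 10 and 20, are evaluated.
#'
#' @param reads Chimeric-read data frame (see [read_chimeric_table()]);
#'   only `chrom` and `pos` are used. Empty input gives an empty result.
#' @param min_support Integer vector of support thresholds (default
#'   `c(10, 20)`).
#' @param window Clustering window in nt (default 100).
#' @return Data frame with one row per breakpoint: `chrom`, `position`
#'   (median of clustered reads), `support`, and one logical column
#'   `pass_ge_<t>` per threshold. Supports sum to `nrow(reads)`.
#' @export
call_integration_breakpoints <- function(reads, min_support = c(10L, 20L),
                                         window = 100L) {
  if (any(min_support < 1L)) stop("min_support must be >= 1", call. = FALSE)
  empty <- data.frame(chrom = character(0), position = numeric(0),
                      support = integer(0), stringsAsFactors = FALSE)
  for (t in min_support) empty[[paste0("pass_ge_", t)]] <- logical(0)
  if (is.null(reads) || nrow(reads) == 0L) return(empty)

  rows <- list()
  for (chr in unique(reads$chrom)) {
    pos <- sort(reads$pos[reads$chrom == chr])
    brk <- c(0L, which(diff(pos) > window), length(pos))
    for (i in seq_len(length(brk) - 1L)) {
      clu <- pos[(brk[i] + 1L):brk[i + 1L]]
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = chr, position = stats::median(clu), support = length(clu),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$chrom, out$position), ]
  rownames(out) <- NULL
  for (t in min_support) out[[paste0("pass_ge_", t)]] <- out$support >= t
  out
}

#' Read a per-position depth table
#'
#' Three-column layout of `samtools depth` output (no header): reference
#' id, 1-based position, depth.
#'
#' @param path Path to the table.
#' @return Data frame `amplicon`, `pos`, `depth`.
#' @export
read_depth_table <- function(path) {
  tab <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 3L) stop("depth table needs 3 columns (ref, pos, depth)", call. = FALSE)
  data.frame(amplicon = tab[[1]], pos = as.integer(tab[[2]]),
             depth = as.numeric(tab[[3]]), stringsAsFactors = FALSE)
}

#' Proportion of coverage lost around a cut site
#'
#' Compares mean read depth in an inner window around the cut with the
#' mean depth in the amplicon's outer flanks:
#' `loss = max(0, 1 - mean(inner) / mean(flanks))`, clipped to `[0, 1]`.
#' Large deletions spanning the cut depress inner coverage, so a uniform
#' profile gives 0 and total dropout gives 1. The statistic is invariant
#' under uniform depth scaling.
#'
#' @param depth Numeric depth vector over the amplicon (position `i` =
#'   base `i`, 1-based), or a data frame from [read_depth_table()]
#'   restricted to one amplicon.
#' @param cut_pos 1-based cut position within the amplicon.
#' @param inner_halfwidth Half-width (nt) of the inner window around the
#'   cut (default 50).
#' @param flank_frac Total fraction of the amplicon used as flanks,
#'   split between the two outer ends (default 0.2, i.e. the outer 10
#'   percent on each side).
#' @return Proportion of lost coverage in `[0, 1]`.
#' @export
coverage_loss <- function(depth, cut_pos, inner_halfwidth = 50L,
                          flank_frac = 0.2) {
  if (is.data.frame(depth)) {
    if (length(unique(depth$amplicon)) > 1L) {
      stop("depth table spans several amplicons; subset first", call. = FALSE)
    }
    v <- numeric(max(depth$pos))
    v[depth$pos] <- depth$depth
    depth <- v
  }
  n <- length(depth)
  if (n == 0L) stop("empty depth profile", call. = FALSE)
  if (cut_pos < 1L || cut_pos > n) stop("cut position outside the amplicon", call. = FALSE)
  k <- max(1L, floor(n * flank_frac / 2))
  flank_idx <- c(seq_len(k), seq(n - k + 1L, n))
  inner_idx <- max(1L, cut_pos - inner_halfwidth):min(n, cut_pos + inner_halfwidth)
  if (any(flank_idx %in% inner_idx)) {
    stop("flanks overlap the inner window; shrink inner_halfwidth or flank_frac",
         call. = FALSE)
  }
  mf <- mean(depth[flank_idx])
  if (mf <= 0) stop("uncovered amplicon: zero flank depth", call. = FALSE)
  min(max(0, 1 - mean(depth[inner_idx]) / mf), 1)
}
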