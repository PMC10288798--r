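#' Classifier parameters
#'
#' @param mh_min Minimum junction-microhomology length (nt) for a deletion
#'   to be called MMEJ. Default 2: deletions flanked by a repeat of at
#'   least 2 nt are attributed to microhomology-mediated end joining.
#' @param mh_max Maximum microhomology length (nt) considered MMEJ
#'   evidence. Default 25; longer flanking repeats are capped at `mh_max`
#'   and flagged (`mh_capped`), since annealing over much longer homology
#'   resembles single-strand annealing rather than MMEJ.
#' @param repair_window Half-width (nt) of the window around the cut site:
#'   an indel must begin or end within `cut_site +/- repair_window` to be
#'   attributed to the cut. Default 50, the scale of a Sanger amplicon
#'   around the protospacer.
#' @param freq_tolerance Allowed overshoot when per-embryo allele
#'   frequencies are checked against 100 percent (default 0.5, absorbing
#'   rounding in upstream trace-decomposition output).
#' @return A list of class `ClassifierParams`.
#' @export
classifier_params <- function(mh_min = 2L, mh_max = 25L, repair_window = 50L,
                              freq_tolerance = 0.5) {
  mh_min <- as.integer(mh_min); mh_max <- as.integer(mh_max)
  if (!(mh_min >= 1L && mh_min <= mh_max)) {
    stop("need 1 <= mh_min <= mh_max", call. = FALSE)
  }
  stopifnot(repair_window >= 1, freq_tolerance >= 0)
  structure(list(mh_min = mh_min, mh_max = mh_max,
                 repair_window = as.integer(repair_window),
                 freq_tolerance = freq_tolerance),
            class = "ClassifierParams")
}

#' Measure junction microhomology of a canonical deletion
#'
#' The junction microhomology of a deletion is the repeated sequence
#' present at both deletion boundaries — equivalently, its placement
#' ambiguity on the reference. The interval must already be left-normalized
#' (see [normalize_deletion()]); the reported length is capped at
#' `params$mh_max` and the repeated sequence is read at the left boundary.
#' Lengths below `params$mh_min` are reported as-is; thresholding is the
#' caller's (classifier's) job.
#'
#' @param locus A [locus()].
#' @param start,end Canonical (left-most) 0-based half-open deletion interval.
#' @param params [classifier_params()].
#' @return List with `mh_length` (integer), `mh_sequence` (string) and
#'   `mh_capped` (TRUE when the flanking repeat exceeded `mh_max`).
#' @examples
#' loc <- locus("toy", "GGGCATCATGGG")
#' detect_microhomology(loc, 3, 6)   # 3 nt, "CAT"
#' @export
detect_microhomology <- function(locus, start, end, params = classifier_params()) {
  stopifnot(inherits(params, "ClassifierParams"))
  norm <- normalize_deletion(locus, start, end)
  if (norm$start != start || norm$end != end) {
    stop("deletion interval must be left-normalized first", call. = FALSE)
  }
  raw <- norm$ambiguity_span
  len <- min(raw, params$mh_max)
  list(mh_length = as.integer(len),
       mh_sequence = if (len > 0L) substr(locus$sequence, start + 1L, start + len) else "",
       mh_capped = raw > params$mh_max)
}

#' Describe one observed allele's indel
#'
#' @param kind One of `"deletion"`, `"insertion"`, `"delins"`,
#'   `"substitution"`, `"none"`.
#' @param del_start,del_end 0-based half-open interval of deleted (or, for
#'   a substitution, replaced) reference bases. For an insertion,
#'   `del_start` is the insertion boundary and `del_end == del_start`.
#' @param ins_seq Inserted (or replacement) sequence; empty unless the kind
#'   carries one.
#' @return A list of class `IndelDescriptor`.
#' @export
indel_descriptor <- function(kind = c("deletion", "insertion", "delins",
                                      "substitution", "none"),
                             del_start = NA_integer_, del_end = NA_integer_,
                             ins_seq = "") {
  kind <- match.arg(kind)
  del_start <- as.integer(del_start); del_end <- as.integer(del_end)
  ins_seq <- toupper(as.character(ins_seq))
  if (is.na(ins_seq)) ins_seq <- ""
  has_del <- kind %in% c("deletion", "delins", "substitution")
  has_ins <- kind %in% c("insertion", "delins", "substitution")
  if (has_del && (is.na(del_start) || is.na(del_end) || del_end <= del_start)) {
    stop("kind '", kind, "' requires a non-empty del interval", call. = FALSE)
  }
  if (kind == "insertion") {
    if (is.na(del_start)) stop("insertion requires a position (del_start)", call. = FALSE)
    del_end <- del_start
  }
  if (has_ins && !grepl("^[ACGT]+$", ins_seq)) {
    stop("kind '", kind, "' requires a non-empty ins_seq over {A,C,G,T}", call. = FALSE)
  }
  if (!has_ins && nzchar(ins_seq)) {
    stop("kind '", kind, "' must not carry ins_seq", call. = FALSE)
  }
  if (kind == "none") { del_start <- NA_integer_; del_end <- NA_integer_ }
  structure(list(kind = kind, del_start = del_start, del_end = del_end,
                 ins_seq = ins_seq),
            class = "IndelDescriptor")
}

#' Classify one allele into a repair category
#'
#' Applies, in order:
#' \enumerate{
#'   \item `UNEDITED` when no indel is present;
#'   \item attribution: after left-normalizing any deletion, the indel must
#'     begin or end within `repair_window` of the cut site, else the call
#'     is `unattributable` (reported but excluded from category totals);
#'   \item `HDR` when the allele reproduces the locus's programmed edit
#'     exactly (same kind, same interval, same written-in sequence);
#'   \item `NHEJ` when any insertion occurred (insertion or delins), for a
#'     substitution that is not the programmed edit (templateless
#'     mutagenic end joining), for a single-base deletion, or for a
#'     deletion whose junction microhomology is shorter than `mh_min`;
#'   \item `MMEJ` for a pure deletion of at least 2 nt whose junction
#'     microhomology lies in `[mh_min, mh_max]`.
#' }
#' A substitution that overlaps a programmed substitution without matching
#' it exactly is reported `unattributable` (imperfect HDR), never HDR.
#'
#' @param indel An [indel_descriptor()].
#' @param locus A [locus()] (its `donor_edit`, if any, defines HDR).
#' @param cut_site 0-based cut boundary, or a `GuideRecord`.
#' @param params [classifier_params()].
#' @return A list of class `RepairCall`: `category` (`"NHEJ"`, `"MMEJ"`,
#'   `"HDR"`, `"UNEDITED"`, `"unattributable"`), `mh_length`,
#'   `mh_sequence`, `mh_capped`, and the canonical deletion interval
#'   (`canon_del_start`, `canon_del_end`, `NA` when no deletion).
#' @export
classify_repair <- function(indel, locus, cut_site, params = classifier_params()) {
  stopifnot(inherits(indel, "IndelDescriptor"), inherits(locus, "Locus"),
            inherits(params, "ClassifierParams"))
  if (inherits(cut_site, "GuideRecord")) cut_site <- cut_site$cut_site
  cut_site <- as.integer(cut_site)

  call0 <- function(category, mh_length = 0L, mh_sequence = "",
                    mh_capped = FALSE, s = NA_integer_, e = NA_integer_) {
    structure(list(category = category, mh_length = as.integer(mh_length),
                   mh_sequence = mh_sequence, mh_capped = mh_capped,
                   canon_del_start = s, canon_del_end = e),
              class = "RepairCall")
  }

  if (indel$kind == "none") return(call0("UNEDITED"))

  # canonical coordinates for attribution (placement-invariant)
  s <- indel$del_start; e <- indel$del_end
  mh <- NULL
  if (indel$kind == "deletion") {
    norm <- normalize_deletion(locus, s, e)
    s <- norm$start; e <- norm$end
    mh <- detect_microhomology(locus, s, e, params)
  } else if (indel$kind %in% c("delins", "substitution")) {
    if (s < 0L || e > locus_length(locus)) {
      stop("indel interval out of locus bounds", call. = FALSE)
    }
  } else { # insertion
    if (s < 0L || s > locus_length(locus)) {
      stop("insertion position out of locus bounds", call. = FALSE)
    }
  }

  w <- params$repair_window
  attributable <- abs(s - cut_site) <= w || abs(e - cut_site) <= w
  if (!attributable) return(call0("unattributable"))

  donor <- locus$donor_edit
  if (!is.null(donor)) {
    donor_kind <- if (donor$type == "substitution") "substitution" else "insertion"
    exact <- indel$kind == donor_kind &&
      identical(indel$del_start, donor$start) &&
      identical(indel$del_end, donor$end) &&
      identical(indel$ins_seq, donor$replacement)
    if (exact) return(call0("HDR"))
    if (indel$kind == "substitution" && donor_kind == "substitution" &&
        indel$del_start < donor$end && donor$start < indel$del_end) {
      return(call0("unattributable"))  # imperfect HDR at the donor site
    }
  }

  if (indel$kind %in% c("insertion", "delins", "substitution")) return(call0("NHEJ"))

  # pure deletion
  if (e - s == 1L) {
    return(call0("NHEJ", mh$mh_length, mh$mh_sequence, mh$mh_capped, s, e))
  }
  if (mh$mh_length >= params$mh_min && mh$mh_length <= params$mh_max) {
    return(call0("MMEJ", mh$mh_length, mh$mh_sequence, mh$mh_capped, s, e))
  }
  call0("NHEJ", mh$mh_length, mh$mh_sequence, mh$mh_capped, s, e)
}

# resolve the Locus and cut site for one guide_id
.guide_context <- function(guide_id, loci, guides) {
  i <- match(guide_id, guides$guide_id)
  if (is.na(i)) stop("unknown guide_id '", guide_id, "'", call. = FALSE)
  loc <- if (inherits(loci, "Locus")) loci else loci[[guides$locus_name[i]]]
  if (is.null(loc)) stop("unknown locus '", guides$locus_name[i], "'", call. = FALSE)
  list(locus = loc, cut_site = guides$cut_site[i])
}

#' Classify a table of allele observations
#'
#' Vectorized front end to [classify_repair()]: one row in, one repair
#' call out, with the input columns preserved.
#'
#' @param alleles Data frame with columns `embryo_id`, `guide_id`, `kind`,
#'   `del_start`, `del_end`, `ins_seq`, `frequency_pct` (the layout
#'   produced by Sanger-trace decomposition export or by
#'   [simulate_cohort()]). Coordinates 0-based half-open; see
#'   [read_allele_table()] for 1-based input.
#' @param loci Named list of loci (or a single `Locus`).
#' @param guides Located guide data frame (see [read_guide_table()] or
#'   [simulate_cohort()]).
#' @param params [classifier_params()].
#' @return The input with columns `category`, `mh_length`, `mh_sequence`,
#'   `mh_capped`, `canon_del_start`, `canon_del_end` appended.
#' @export
classify_alleles <- function(alleles, loci, guides, params = classifier_params()) {
  need <- c("embryo_id", "guide_id", "kind", "del_start", "del_end",
            "ins_seq", "frequency_pct")
  if (!all(need %in% names(alleles))) {
    stop("allele table requires columns: ", paste(need, collapse = ", "), call. = FALSE)
  }
  n <- nrow(alleles)
  category <- character(n); mh_length <- integer(n); mh_sequence <- character(n)
  mh_capped <- logical(n)
  cs <- rep(NA_integer_, n); ce <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    ctx <- .guide_context(alleles$guide_id[i], loci, guides)
    ind <- indel_descriptor(alleles$kind[i], alleles$del_start[i],
                            alleles$del_end[i],
                            if (is.na(alleles$ins_seq[i])) "" else alleles$ins_seq[i])
    rc <- classify_repair(ind, ctx$locus, ctx$cut_site, params)
    category[i] <- rc$category; mh_length[i] <- rc$mh_length
    mh_sequence[i] <- rc$mh_sequence; mh_capped[i] <- rc$mh_capped
    cs[i] <- rc$canon_del_start; ce[i] <- rc$canon_del_end
  }
  cbind(alleles,
        data.frame(category = category, mh_length = mh_length,
                   mh_sequence = mh_sequence, mh_capped = mh_capped,
                   canon_del_start = cs, canon_del_end = ce,
                   stringsAsFactors = FALSE))
}

#' Per-embryo repair profiles
#'
#' Sums allele frequencies by repair category within each embryo and
#' computes the editing efficiency on the attributable mass:
#' `E = 100 * (f_NHEJ + f_MMEJ + f_HDR) / (f_NHEJ + f_MMEJ + f_HDR + f_UNEDITED)`.
#' When every allele sums to 100 this is simply `100 - f_UNEDITED`.
#'
#' @param calls Output of [classify_alleles()].
#' @param params [classifier_params()] (its `freq_tolerance` bounds the
#'   per-embryo frequency sum check).
#' @return Data frame with one row per (embryo, guide): `f_nhej`, `f_mmej`,
#'   `f_hdr`, `f_unedited`, `f_unattributable`, `efficiency`.
#' @export
embryo_profiles <- function(calls, params = classifier_params()) {
  if (nrow(calls) == 0L) stop("empty observation table", call. = FALSE)
  key <- paste(calls$embryo_id, calls$guide_id, sep = "\r")
  rows <- lapply(split(seq_len(nrow(calls)), key), function(idx) {
    sub <- calls[idx, , drop = FALSE]
    tot <- sum(sub$frequency_pct)
    if (tot > 100 + params$freq_tolerance) {
      stop("malformed allele table: embryo '", sub$embryo_id[1],
           "' frequencies sum to ", format(tot), call. = FALSE)
    }
    f <- function(cat) sum(sub$frequency_pct[sub$category == cat])
    fn <- f("NHEJ"); fm <- f("MMEJ"); fh <- f("HDR"); fu <- f("UNEDITED")
    fx <- f("unattributable")
    attrib <- fn + fm + fh + fu
    data.frame(embryo_id = sub$embryo_id[1], guide_id = sub$guide_id[1],
               f_nhej = fn, f_mmej = fm, f_hdr = fh, f_unedited = fu,
               f_unattributable = fx,
               efficiency = if (attrib > 0) 100 * (fn + fm + fh) / attrib else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Classify one embryo's observations end to end
#'
#' Convenience wrapper: classifies the alleles of a single embryo and
#' returns its one-row profile. All observations must share one embryo id
#' and one guide.
#'
#' @inheritParams classify_alleles
#' @return One-row data frame as in [embryo_profiles()].
#' @export
classify_embryo <- function(alleles, loci, guides, params = classifier_params()) {
  if (is.null(nrow(alleles)) || nrow(alleles) == 0L) {
    stop("empty observation list", call. = FALSE)
  }
  if (length(unique(alleles$embryo_id)) != 1L ||
      length(unique(alleles$guide_id)) != 1L) {
    stop("observations must share one embryo id and one guide", call. = FALSE)
  }
  embryo_profiles(classify_alleles(alleles, loci, guides, params), params)
}

#' Read an allele observation table
#'
#' Delimited text with header columns `embryo_id`, `guide_id`, `kind`,
#' `del_start`, `del_end`, `ins_seq`, `frequency_pct` — the shape of a
#' Sanger-trace decomposition export, one row per allele. With
#' `one_based = TRUE`, 1-based inclusive `del_start..del_end` coordinates
#' are converted to the package's 0-based half-open convention at the
#' boundary; deletions are re-normalized downstream regardless, so the
#' reported placement need not be left-aligned.
#'
#' @param path Path to the table.
#' @param one_based Input coordinates are 1-based inclusive (default FALSE).
#' @param sep Field separator (default tab).
#' @return Data frame ready for [classify_alleles()].
#' @export
read_allele_table <- function(path, one_based = FALSE, sep = "\t") {
  tab <- utils::read.delim(path, sep = sep, stringsAsFactors = FALSE)
  need <- c("embryo_id", "guide_id", "kind", "del_start", "del_end",
            "ins_seq", "frequency_pct")
  if (!all(need %in% names(tab))) {
    stop("allele table requires columns: ", paste(need, collapse = ", "), call. = FALSE)
  }
  tab$ins_seq[is.na(tab$ins_seq)] <- ""
  if (one_based) {
    shift <- tab$kind %in% c("deletion", "delins", "substitution", "insertion")
    tab$del_start[shift] <- tab$del_start[shift] - 1L
    ins <- tab$kind == "insertion"
    tab$del_end[ins] <- tab$del_start[ins]
  }
  tab
}

#' Write per-allele repair calls
#'
#' @param calls Output of [classify_alleles()].
#' @param path Output path (tab-delimited, with header).
#' @export
write_repair_calls <- function(calls, path) {
  utils::write.table(calls, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
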