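#' @importFrom Biostrings DNAString readDNAStringSet reverseComplement matchPattern
#' @importFrom utils read.delim write.table
#' @importFrom stats median rexp rgeom runif
NULL

#' Construct a reference locus
#'
#' A `Locus` bundles a named reference sequence with an optional programmed
#' donor edit. All coordinates on a locus are 0-based, half-open: position
#' `i` names the boundary *before* the (i+1)-th base, and an interval
#' `[start, end)` covers bases `start .. end - 1`.
#'
#' @param name Locus identifier (single non-empty string).
#' @param sequence Nucleotide string over `A`, `C`, `G`, `T` (case is
#'   normalized to upper).
#' @param donor_edit Optional [programmed_edit()] describing the intended
#'   HDR outcome at this locus.
#' @return An object of class `Locus`: a list with elements `name`,
#'   `sequence` and `donor_edit`.
#' @examples
#' loc <- locus("toy", "GGGCATCATGGG")
#' locus_length(loc)
#' @export
locus <- function(name, sequence, donor_edit = NULL) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  sequence <- toupper(as.character(sequence))
  if (!grepl("^[ACGT]+$", sequence)) {
    stop("locus sequence must be a non-empty string over {A,C,G,T}", call. = FALSE)
  }
  obj <- structure(list(name = name, sequence = sequence, donor_edit = NULL),
                   class = "Locus")
  if (!is.null(donor_edit)) {
    validate_edit_on_locus(donor_edit, obj)
    obj$donor_edit <- donor_edit
  }
  obj
}

#' @rdname locus
#' @param x A `Locus`.
#' @export
locus_length <- function(x) {
  stopifnot(inherits(x, "Locus"))
  nchar(x$sequence)
}

#' @export
print.Locus <- function(x, ...) {
  n <- nchar(x$sequence)
  shown <- if (n > 50) paste0(substr(x$sequence, 1, 50), "...") else x$sequence
  cat(sprintf("Locus '%s' (%d nt): %s\n", x$name, n, shown))
  if (!is.null(x$donor_edit)) {
    e <- x$donor_edit
    cat(sprintf("  programmed %s [%d,%d) -> %s\n", e$type, e$start, e$end,
                e$replacement))
  }
  invisible(x)
}

#' Describe a programmed (donor-templated) edit
#'
#' The intended HDR outcome at a locus: either a substitution replacing the
#' reference bases in `[start, end)` by `replacement`, or an insertion of
#' `replacement` at the boundary `start` (for insertions `end == start`).
#'
#' @param type `"substitution"` or `"insertion"`.
#' @param start,end 0-based half-open interval on the locus. For an
#'   insertion the interval is empty (`end == start`).
#' @param replacement Non-empty nucleotide string written in by HDR.
#' @return An object of class `ProgrammedEdit`.
#' @examples
#' programmed_edit("substitution", 14, 20, "GAATTC")  # EcoRI knock-in
#' @export
programmed_edit <- function(type = c("substitution", "insertion"),
                            start, end = start, replacement) {
  type <- match.arg(type)
  start <- as.integer(start); end <- as.integer(end)
  replacement <- toupper(as.character(replacement))
  if (!grepl("^[ACGT]+$", replacement)) {
    stop("replacement must be a non-empty string over {A,C,G,T}", call. = FALSE)
  }
  if (type == "insertion" && end != start) {
    stop("an insertion has an empty interval (end == start)", call. = FALSE)
  }
  if (type == "substitution" && end <= start) {
    stop("a substitution replaces a non-empty interval (end > start)", call. = FALSE)
  }
  structure(list(type = type, start = start, end = end,
                 replacement = replacement),
            class = "ProgrammedEdit")
}

validate_edit_on_locus <- function(edit, locus) {
  stopifnot(inherits(edit, "ProgrammedEdit"))
  if (edit$start < 0L || edit$end > nchar(locus$sequence)) {
    stop("programmed edit interval lies outside the locus", call. = FALSE)
  }
  invisible(TRUE)
}

#' Read reference loci from a FASTA file
#'
#' Each FASTA record becomes one [locus()]; the record id (first word of
#' the header) is the locus name.
#'
#' @param path Path to a (possibly multi-record) FASTA file.
#' @return Named list of `Locus` objects.
#' @export
read_loci <- function(path) {
  set <- Biostrings::readDNAStringSet(path)
  nm <- vapply(strsplit(names(set), "\\s+"), `[`, character(1), 1L)
  out <- lapply(seq_along(set), function(i) locus(nm[i], as.character(set[[i]])))
  names(out) <- nm
  out
}

# -- guide location ----------------------------------------------------------

new_guide_record <- function(locus_name, protospacer, strand, pam_start, cut_site) {
  structure(list(locus_name = locus_name, protospacer = protospacer,
                 strand = strand, pam_start = as.integer(pam_start),
                 cut_site = as.integer(cut_site)),
            class = "GuideRecord")
}

#' @export
print.GuideRecord <- function(x, ...) {
  cat(sprintf("GuideRecord: %s on '%s' (%s), PAM start %d, cut site %d\n",
              x$protospacer, x$locus_name, x$strand, x$pam_start, x$cut_site))
  invisible(x)
}

#' Locate a protospacer and its cut site on a locus
#'
#' Scans both strands for the protospacer immediately 5' of a PAM match
#' (IUPAC pattern, default `NGG`) and places the blunt Cas9 cut
#' `cut_offset` nt 5' of the PAM — for SpCas9 the boundary between
#' protospacer positions 17 and 18. Guides found on the minus strand are
#' reported in locus-forward coordinates; `pam_start` is the forward-strand
#' start of the PAM trinucleotide on either strand.
#'
#' @param locus A [locus()].
#' @param protospacer Protospacer sequence (20 nt for SpCas9; any length
#'   longer than `cut_offset` is accepted).
#' @param pam IUPAC PAM pattern on the guide strand (default `"NGG"`).
#' @param multiple `"error"` (default) fails on ambiguous placement;
#'   `"all"` returns every placement as a list for the caller to
#'   disambiguate.
#' @param cut_offset Cut-site distance in nt 5' of the PAM (default 3,
#'   standard SpCas9 blunt cut).
#' @return A `GuideRecord` (or a list of them when `multiple = "all"`),
#'   with `cut_site` a 0-based boundary position strictly inside the locus.
#' @examples
#' loc <- locus("toy", "AAAAGCATGCATGCATGCATGCATAGGTTTT")
#' locate_guide(loc, "GCATGCATGCATGCATGCAT")
#' @export
locate_guide <- function(locus, protospacer, pam = "NGG",
                         multiple = c("error", "all"), cut_offset = 3L) {
  multiple <- match.arg(multiple)
  stopifnot(inherits(locus, "Locus"))
  protospacer <- toupper(as.character(protospacer))
  if (!grepl("^[ACGT]+$", protospacer) || nchar(protospacer) <= cut_offset) {
    stop("protospacer must be an ACGT string longer than cut_offset", call. = FALSE)
  }
  subject <- Biostrings::DNAString(locus$sequence)
  pat <- Biostrings::DNAString(paste0(protospacer, pam))
  np <- nchar(protospacer); npam <- nchar(pam)
  L <- nchar(locus$sequence)

  hits <- list()
  fwd <- Biostrings::matchPattern(pat, subject, fixed = FALSE)
  for (p1 in Biostrings::start(fwd)) {
    p0 <- p1 - 1L
    hits[[length(hits) + 1L]] <- new_guide_record(
      locus$name, protospacer, "+",
      pam_start = p0 + np, cut_site = p0 + np - cut_offset)
  }
  rev <- Biostrings::matchPattern(Biostrings::reverseComplement(pat), subject,
                                  fixed = FALSE)
  for (q1 in Biostrings::start(rev)) {
    q0 <- q1 - 1L
    hits[[length(hits) + 1L]] <- new_guide_record(
      locus$name, protospacer, "-",
      pam_start = q0, cut_site = q0 + npam + cut_offset)
  }

  if (length(hits) == 0L) stop("guide not found", call. = FALSE)
  for (h in hits) {
    if (h$cut_site <= 0L || h$cut_site >= L) {
      stop("cut site falls on a locus boundary; extend the reference", call. = FALSE)
    }
  }
  if (multiple == "all") return(hits)
  if (length(hits) > 1L) stop("ambiguous guide placement", call. = FALSE)
  hits[[1L]]
}

#' Read a guide table
#'
#' Tab-delimited with header columns `guide_id`, `locus`, `protospacer` and
#' optionally `pam` (default `NGG`). Each guide is located on its locus
#' with [locate_guide()].
#'
#' @param path Path to the table.
#' @param loci Named list of loci, as returned by [read_loci()].
#' @return A data frame with one located guide per row: `guide_id`,
#'   `locus_name`, `protospacer`, `strand`, `pam_start`, `cut_site`.
#' @export
read_guide_table <- function(path, loci) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("guide_id", "locus", "protospacer")
  if (!all(need %in% names(tab))) {
    stop("guide table requires columns: ", paste(need, collapse = ", "), call. = FALSE)
  }
  if (is.null(tab$pam)) tab$pam <- "NGG"
  recs <- lapply(seq_len(nrow(tab)), function(i) {
    loc <- loci[[tab$locus[i]]]
    if (is.null(loc)) stop("unknown locus '", tab$locus[i], "'", call. = FALSE)
    g <- locate_guide(loc, tab$protospacer[i], pam = tab$pam[i])
    data.frame(guide_id = tab$guide_id[i], locus_name = g$locus_name,
               protospacer = g$protospacer, strand = g$strand,
               pam_start = g$pam_start, cut_site = g$cut_site,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, recs)
}

# -- deletion canonicalization -----------------------------------------------

#' Left-normalize a deletion and measure its placement ambiguity
#'
#' A deletion inside a repeat can be reported at several coordinates that
#' all produce the same edited sequence. The canonical placement is the
#' left-most one; the ambiguity span is the number of alternative
#' placements minus one, which equals the length of the repeated junction
#' sequence (the microhomology) shared by the two deletion boundaries.
#'
#' @param locus A [locus()].
#' @param start,end 0-based half-open deletion interval, non-empty and
#'   within the locus.
#' @return A list with integer elements `start`, `end` (canonical
#'   placement) and `ambiguity_span`.
#' @examples
#' loc <- locus("toy", "GGGCATCATGGG")
#' normalize_deletion(loc, 6, 9)   # -> [3,6), span 3
#' @export
normalize_deletion <- function(locus, start, end) {
  stopifnot(inherits(locus, "Locus"))
  start <- as.integer(start); end <- as.integer(end)
  L <- nchar(locus$sequence)
  if (is.na(start) || is.na(end) || start < 0L || end > L || end <= start) {
    stop("deletion interval out of bounds or empty", call. = FALSE)
  }
  v <- utf8ToInt(locus$sequence)
  s <- start; e <- end
  # left-shift while the base before the interval equals the base before its end
  while (s > 0L && v[s] == v[e]) {
    s <- s - 1L
    e <- e - 1L
  }
  kmax <- L - e
  span <- 0L
  if (kmax > 0L) {
    idx <- seq_len(kmax)
    cmp <- v[s + idx] == v[e + idx]
    bad <- which(!cmp)
    span <- if (length(bad)) bad[1L] - 1L else kmax
  }
  list(start = s, end = e, ambiguity_span = as.integer(span))
}

# apply a deletion to a sequence string (0-based half-open interval)
apply_deletion <- function(sequence, start, end) {
  paste0(substr(sequence, 1L, start), substr(sequence, end + 1L, nchar(sequence)))
}
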