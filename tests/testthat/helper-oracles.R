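# Independent brute-force oracles and fixture builders.
# These deliberately avoid the package's own normalize/detect code paths:
# placements are enumerated exhaustively by applying each candidate deletion
# and comparing edited strings.

oracle_delete <- function(sequence, start, end) {
  paste0(substring(sequence, 1, start),
         substring(sequence, end + 1, nchar(sequence)))
}

# all equal-length placements producing the same edited string
oracle_placements <- function(sequence, start, end) {
  len <- end - start
  L <- nchar(sequence)
  target <- oracle_delete(sequence, start, end)
  hits <- integer(0)
  for (s in 0:(L - len)) {
    if (oracle_delete(sequence, s, s + len) == target) hits <- c(hits, s)
  }
  hits
}

# canonical start, ambiguity span (= placements - 1) and junction repeat
oracle_mh <- function(sequence, start, end) {
  hits <- oracle_placements(sequence, start, end)
  s0 <- min(hits)
  span <- length(hits) - 1L
  list(canonical_start = s0, canonical_end = s0 + (end - start),
       span = span,
       mh_sequence = if (span > 0) substr(sequence, s0 + 1, s0 + span) else "")
}

oracle_revcomp <- function(x) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", x), "")[[1]]), collapse = "")
}

# brute scan of both strands for protospacer + NGG, returning cut boundaries
oracle_guide_sites <- function(sequence, proto, pam_regex = "[ACGT]GG") {
  L <- nchar(sequence)
  np <- nchar(proto)
  sites <- list()
  for (p in 0:(L - np - 3)) {
    if (substr(sequence, p + 1, p + np) == proto &&
        grepl(paste0("^", pam_regex, "$"),
              substr(sequence, p + np + 1, p + np + 3))) {
      sites[[length(sites) + 1]] <- list(strand = "+", cut = p + np - 3L)
    }
  }
  rc <- oracle_revcomp(sequence)
  for (p in 0:(L - np - 3)) {
    if (substr(rc, p + 1, p + np) == proto &&
        grepl(paste0("^", pam_regex, "$"), substr(rc, p + np + 1, p + np + 3))) {
      # cut on rc at boundary p+np-3; mirror back to forward coordinates
      sites[[length(sites) + 1]] <- list(strand = "-", cut = L - (p + np - 3L))
    }
  }
  sites
}

# random locus; a small alphabet makes repeats (hence microhomology) common
rand_seq <- function(n, k = 4) {
  paste(sample(c("A", "C", "G", "T")[seq_len(k)], n, replace = TRUE),
        collapse = "")
}

rand_deletion <- function(L, max_len = 12) {
  len <- sample.int(min(max_len, L - 2), 1)
  s <- sample.int(L - len, 1) - 1L
  c(s, s + len)
}

# one-guide fixture used across classifier tests: protospacer + AGG PAM,
# cut boundary at 22, and a planted CATCAT repeat downstream so an MMEJ
# deletion ([29,32), junction "CAT") is available by construction
toy_fixture <- function(donor = NULL) {
  seq <- paste0("TTACG", "GCTTACGGATCGTTAAGCTG", "AGG", "ACATCATG",
                "TTGACCGTA")
  loc <- locus("toy_locus", seq, donor_edit = donor)
  g <- locate_guide(loc, "GCTTACGGATCGTTAAGCTG", pam = "NGG")
  guides <- data.frame(guide_id = "sg_toy", locus_name = "toy_locus",
                       protospacer = g$protospacer, strand = g$strand,
                       pam_start = g$pam_start, cut_site = g$cut_site,
                       stringsAsFactors = FALSE)
  list(loc = loc, guides = guides, cut = g$cut_site)
}

allele_row <- function(embryo, kind, ds = NA, de = NA, ins = "", freq = 100,
                       guide = "sg_toy") {
  data.frame(embryo_id = embryo, guide_id = guide, kind = kind,
             del_start = ds, del_end = de, ins_seq = ins,
             frequency_pct = freq, stringsAsFactors = FALSE)
}
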