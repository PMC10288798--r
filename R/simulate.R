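#' Configure a synthetic embryo-editing cohort
#'
#' The generative model emulates the output shape of amplicon genotyping
#' of injected embryos: per embryo a small number of mosaic alleles with
#' frequencies summing to 100 percent, each allele drawn from one of five
#' outcome categories (unedited, NHEJ insertion, NHEJ deletion, MMEJ
#' deletion, HDR) and realized as a concrete indel on a simulated locus.
#' Every MMEJ deletion removes exactly one copy of a repeat pair planted
#' in the locus, so its junction microhomology is known by construction;
#' NHEJ deletions are rejection-sampled until their junction ambiguity is
#' below `mh_min` (or the deletion is a single base). Identical configs
#' give byte-identical output.
#'
#' @param seed Integer seed; mandatory, drives all randomness.
#' @param n_guides Number of guides (each with its own simulated locus).
#' @param n_embryos Embryos per guide.
#' @param allele_count_range Integer range (inclusive) for the number of
#'   mosaic alleles per embryo; drawn uniformly. Default 1--4.
#' @param category_weights Named simplex over `UNEDITED`, `NHEJ_INS`,
#'   `NHEJ_DEL`, `MMEJ_DEL`, `HDR` (must sum to 1). `HDR > 0` requires a
#'   programmed edit (one is planted automatically: a 6-nt EcoRI-style
#'   `GAATTC` substitution spanning the cut).
#' @param mh_lengths,mh_probs Support (within 2--25 nt) and weights of the
#'   MMEJ microhomology-length distribution; default uniform on 2--8,
#'   which is the widest support whose planted cassettes all fit inside
#'   the default +/-50 nt repair window on one locus.
#' @param deletion_mean,deletion_cap Geometric mean (nt) and cap of NHEJ
#'   deletion lengths (defaults 6 and 30).
#' @param insertion_mean,insertion_cap Geometric mean and cap of NHEJ
#'   insertion lengths (defaults 2 and 10).
#' @param locus_length Simulated locus length in nt (default 240).
#' @param repair_window Attribution half-window the cohort is built for
#'   (default 50); planted deletions are guaranteed to start or end within
#'   it.
#' @param mh_min Junction-ambiguity bound used when rejection-sampling
#'   NHEJ deletions (default 2, matching [classifier_params()]).
#' @return A list of class `SimulationConfig`.
#' @export
simulation_config <- function(seed,
                              n_guides = 88L,
                              n_embryos = 10L,
                              allele_count_range = c(1L, 4L),
                              category_weights = c(UNEDITED = 0.30,
                                                   NHEJ_INS = 0.15,
                                                   NHEJ_DEL = 0.25,
                                                   MMEJ_DEL = 0.30,
                                                   HDR = 0),
                              mh_lengths = 2:8, mh_probs = NULL,
                              deletion_mean = 6, deletion_cap = 30L,
                              insertion_mean = 2, insertion_cap = 10L,
                              locus_length = 240L,
                              repair_window = 50L,
                              mh_min = 2L) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  cats <- c("UNEDITED", "NHEJ_INS", "NHEJ_DEL", "MMEJ_DEL", "HDR")
  if (!all(cats %in% names(category_weights))) {
    stop("category_weights must be named: ", paste(cats, collapse = ", "), call. = FALSE)
  }
  category_weights <- category_weights[cats]
  if (any(category_weights < 0) || abs(sum(category_weights) - 1) > 1e-8) {
    stop("category_weights must be a simplex (nonnegative, sum 1)", call. = FALSE)
  }
  mh_lengths <- as.integer(mh_lengths)
  if (any(mh_lengths < 2L) || any(mh_lengths > 25L)) {
    stop("mh_lengths must lie in 2..25 nt", call. = FALSE)
  }
  if (is.null(mh_probs)) mh_probs <- rep(1, length(mh_lengths))
  stopifnot(length(mh_probs) == length(mh_lengths), all(mh_probs >= 0),
            sum(mh_probs) > 0)
  structure(list(seed = as.integer(seed), n_guides = as.integer(n_guides),
                 n_embryos = as.integer(n_embryos),
                 allele_count_range = as.integer(allele_count_range),
                 category_weights = category_weights,
                 mh_lengths = mh_lengths, mh_probs = mh_probs / sum(mh_probs),
                 deletion_mean = deletion_mean, deletion_cap = as.integer(deletion_cap),
                 insertion_mean = insertion_mean, insertion_cap = as.integer(insertion_cap),
                 locus_length = as.integer(locus_length),
                 repair_window = as.integer(repair_window),
                 mh_min = as.integer(mh_min)),
            class = "SimulationConfig")
}

.BASES <- c("A", "C", "G", "T")

.rand_bases <- function(n) sample(.BASES, n, replace = TRUE)

# geometric length with support >= 1, given mean and cap
.rgeom_len <- function(mean, cap) min(1L + stats::rgeom(1L, 1 / mean), cap)

#' Generate one simulated locus with planted microhomology cassettes
#'
#' Builds a random locus carrying a unique protospacer + NGG site at its
#' center and, flanking the cut, one repeat cassette `R-filler-R` per
#' microhomology length the config can draw. Deleting the first repeat
#' copy plus the filler of cassette `m` leaves a junction with exactly
#' `m` nt of microhomology; cassette boundaries are base-constrained so
#' the planted ambiguity can neither shrink nor extend, and each planted
#' deletion begins or ends within the configured repair window of the
#' cut. Every cassette is verified at build time with an exhaustive
#' placement enumeration independent of [detect_microhomology()].
#'
#' @param config A [simulation_config()].
#' @param name Locus name.
#' @param set_seed Seed the RNG from `config$seed` (default TRUE). Callers
#'   generating many loci in one stream ([simulate_cohort()]) pass FALSE.
#' @return List with elements `locus` ([locus()], carrying the programmed
#'   edit when the config's HDR weight is positive), `guide` (located
#'   `GuideRecord`) and `planted` (data frame `mh_length`, `del_start`,
#'   `del_end` of the canonical planted deletions).
#' @export
generate_locus <- function(config, name = "locus_1", set_seed = TRUE) {
  stopifnot(inherits(config, "SimulationConfig"))
  if (set_seed) set.seed(config$seed)
  L <- config$locus_length
  if (L < 60L) stop("locus length must be at least 60 nt", call. = FALSE)
  w <- config$repair_window
  support <- sort(config$mh_lengths[config$mh_probs > 0])
  gap <- 2L; fil <- 2L

  # cassette bookkeeping: alternate sides, ascending m outward on each side
  right_ms <- support[seq_along(support) %% 2L == 1L]
  left_ms <- support[seq_along(support) %% 2L == 0L]
  right_len <- sum(2L * right_ms + gap + fil)
  left_len <- sum(2L * left_ms + gap + fil)
  core <- left_len + 20L + 3L + right_len
  if (core + 10L > L) {
    stop("infeasible config: requested microhomology lengths exceed locus capacity",
         call. = FALSE)
  }

  for (try in 1:25) {
    pad_total <- L - core
    pad_left <- max(5L, pad_total %/% 2L)
    pad_right <- pad_total - pad_left
    proto <- paste(.rand_bases(20L), collapse = "")
    pam <- paste0(sample(.BASES, 1L), "GG")

    seq_chr <- .rand_bases(L)
    p <- pad_left + left_len            # protospacer start (0-based)
    cut <- p + 17L
    seq_chr[(p + 1L):(p + 20L)] <- strsplit(proto, "")[[1]]
    seq_chr[(p + 21L):(p + 23L)] <- strsplit(pam, "")[[1]]

    planted <- data.frame(mh_length = integer(0), del_start = integer(0),
                          del_end = integer(0))
    ok <- TRUE

    # left cassettes: [R F R gap], outermost first; nearest gets smallest m
    pos <- p  # 0-based start of the element to the right of the cassette run
    for (m in left_ms) {              # ascending = nearest-first; walk leftward
      size <- 2L * m + fil + gap
      bs <- pos - size                # cassette start, 0-based
      a <- bs; e <- a + m + fil       # planted canonical deletion [a, e)
      if (e < cut - w || bs < 1L) { ok <- FALSE; break }
      R <- .rand_bases(m); Fl <- .rand_bases(fil)
      seq_chr[(bs + 1L):(bs + m)] <- R
      seq_chr[(bs + m + 1L):(bs + m + fil)] <- Fl
      seq_chr[(bs + m + fil + 1L):(bs + 2L * m + fil)] <- R
      # boundary constraints: no left extension, ambiguity exactly m
      seq_chr[a] <- sample(setdiff(.BASES, seq_chr[e]), 1L)            # base at a-1
      seq_chr[a + 2L * m + fil + 1L] <-
        sample(setdiff(.BASES, seq_chr[a + m + 1L]), 1L)               # base at e+m
      planted <- rbind(planted, data.frame(mh_length = m, del_start = a,
                                           del_end = e))
      pos <- bs
    }
    if (!ok) {
      stop("infeasible config: microhomology cassettes do not fit inside the repair window",
           call. = FALSE)
    }

    # right cassettes: [gap R F R], ascending m outward from the PAM
    pos <- p + 23L
    for (m in right_ms) {
      bs <- pos
      a <- bs + gap; e <- a + m + fil
      if (a > cut + w || e + m + 1L > L) {
        stop("infeasible config: microhomology cassettes do not fit inside the repair window",
             call. = FALSE)
      }
      R <- .rand_bases(m); Fl <- .rand_bases(fil)
      seq_chr[(a + 1L):(a + m)] <- R
      seq_chr[(a + m + 1L):(a + m + fil)] <- Fl
      seq_chr[(a + m + fil + 1L):(a + 2L * m + fil)] <- R
      seq_chr[a] <- sample(setdiff(.BASES, seq_chr[e]), 1L)
      seq_chr[a + 2L * m + fil + 1L] <-
        sample(setdiff(.BASES, seq_chr[a + m + 1L]), 1L)
      planted <- rbind(planted, data.frame(mh_length = m, del_start = a,
                                           del_end = e))
      pos <- bs + gap + 2L * m + fil
    }

    loc <- locus(name, paste(seq_chr, collapse = ""))

    # donor edit: EcoRI-style substitution spanning the cut
    donor <- NULL
    if (config$category_weights[["HDR"]] > 0) {
      if (substr(loc$sequence, cut - 2L, cut + 3L) == "GAATTC") next
      donor <- programmed_edit("substitution", cut - 3L, cut + 3L, "GAATTC")
      loc <- locus(name, loc$sequence, donor_edit = donor)
    }

    # unique protospacer placement, cut where we built it
    g <- tryCatch(locate_guide(loc, proto, pam = "NGG"), error = function(e) NULL)
    if (is.null(g) || g$cut_site != cut || g$strand != "+") next

    # verify every cassette by exhaustive placement enumeration
    good <- TRUE
    for (i in seq_len(nrow(planted))) {
      chk <- .mh_enumerate(loc$sequence, planted$del_start[i], planted$del_end[i])
      if (chk$start != planted$del_start[i] || chk$span != planted$mh_length[i]) {
        good <- FALSE; break
      }
    }
    if (!good) next

    planted <- planted[order(planted$mh_length), , drop = FALSE]
    rownames(planted) <- NULL
    return(list(locus = loc, guide = g, planted = planted))
  }
  stop("failed to generate a valid locus; widen locus_length or simplify the config",
       call. = FALSE)
}

# brute-force placement enumeration (generation-time verification,
# independent of normalize_deletion): all equal-length intervals giving the
# same edited string
.mh_enumerate <- function(sequence, start, end) {
  len <- end - start
  L <- nchar(sequence)
  target <- apply_deletion(sequence, start, end)
  hits <- integer(0)
  for (s in 0:(L - len)) {
    if (apply_deletion(sequence, s, s + len) == target) hits <- c(hits, s)
  }
  list(start = min(hits), span = length(hits) - 1L)
}

#' Simulate an embryo-editing cohort with ground-truth labels
#'
#' Draws, for each guide, a simulated locus ([generate_locus()]) and
#' `n_embryos` embryos; per embryo, a number of mosaic alleles with
#' exponential-spacing frequencies renormalized to sum to exactly 100, and
#' per allele a category from `category_weights` realized as a concrete
#' indel. MMEJ deletions are emitted at a *random* placement among the
#' equivalent ones (exercising downstream left-normalization); their truth
#' microhomology is the planted length. NHEJ deletions are
#' rejection-sampled near the cut until junction ambiguity is below
#' `mh_min` or length is 1; NHEJ insertions insert random sequence at the
#' cut; HDR alleles reproduce the programmed edit exactly.
#'
#' @param config A [simulation_config()].
#' @return List with `loci` (named list), `guides` (located guide data
#'   frame), `alleles` (observation table for [classify_alleles()]),
#'   `truth` (`allele_id`, `true_category`, `true_mh_length`) and
#'   `config`.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "SimulationConfig"))
  set.seed(config$seed)
  weights <- config$category_weights
  cats <- names(weights)
  acr <- config$allele_count_range
  support <- config$mh_lengths; sprob <- config$mh_probs

  loci <- list(); guide_rows <- list()
  al <- list(); tr <- list()

  for (g in seq_len(config$n_guides)) {
    lname <- sprintf("locus_%03d", g)
    gid <- sprintf("sg_%03d", g)
    built <- generate_locus(config, name = lname, set_seed = FALSE)
    loci[[lname]] <- built$locus
    cut <- built$guide$cut_site
    L <- locus_length(built$locus)
    donor <- built$locus$donor_edit
    guide_rows[[g]] <- data.frame(guide_id = gid, locus_name = lname,
                                  protospacer = built$guide$protospacer,
                                  strand = built$guide$strand,
                                  pam_start = built$guide$pam_start,
                                  cut_site = cut, stringsAsFactors = FALSE)

    for (e in seq_len(config$n_embryos)) {
      eid <- sprintf("%s_embryo_%02d", gid, e)
      k <- sample(acr[1]:acr[2], 1L)
      acat <- sample(cats, k, replace = TRUE, prob = weights)
      freq <- stats::rexp(k)
      freq <- 100 * freq / sum(freq)
      for (a in seq_len(k)) {
        aid <- sprintf("%s_a%d", eid, a)
        kind <- "none"; ds <- NA_integer_; de <- NA_integer_; ins <- ""
        true_mh <- 0L
        cat_a <- acat[a]
        if (cat_a == "NHEJ_INS") {
          kind <- "insertion"; ds <- cut; de <- cut
          repeat {
            ins <- paste(.rand_bases(.rgeom_len(config$insertion_mean,
                                                config$insertion_cap)),
                         collapse = "")
            if (is.null(donor) || donor$type != "insertion" ||
                donor$start != cut || !identical(ins, donor$replacement)) break
          }
        } else if (cat_a == "NHEJ_DEL") {
          kind <- "deletion"
          found <- FALSE
          for (it in 1:200) {
            len <- .rgeom_len(config$deletion_mean, config$deletion_cap)
            u <- sample(0:len, 1L)
            s <- cut - u; en <- s + len
            if (s < 1L || en > L - 1L) next
            nz <- normalize_deletion(built$locus, s, en)
            if (len == 1L || nz$ambiguity_span < config$mh_min) {
              ds <- s; de <- en; true_mh <- nz$ambiguity_span
              found <- TRUE; break
            }
          }
          if (!found) {
            stop("config infeasible: NHEJ deletion rejection sampling exhausted",
                 call. = FALSE)
          }
        } else if (cat_a == "MMEJ_DEL") {
          kind <- "deletion"
          m <- if (length(support) == 1L) support else sample(support, 1L, prob = sprob)
          row <- built$planted[match(m, built$planted$mh_length), ]
          shift <- sample(0:m, 1L)  # any equivalent placement
          ds <- row$del_start + shift; de <- row$del_end + shift
          true_mh <- m
        } else if (cat_a == "HDR") {
          if (is.null(donor)) stop("HDR weight > 0 requires a programmed edit",
                                   call. = FALSE)
          kind <- if (donor$type == "substitution") "substitution" else "insertion"
          ds <- donor$start; de <- donor$end; ins <- donor$replacement
        }
        al[[length(al) + 1L]] <- data.frame(
          allele_id = aid, embryo_id = eid, guide_id = gid, kind = kind,
          del_start = ds, del_end = de, ins_seq = ins,
          frequency_pct = freq[a], stringsAsFactors = FALSE)
        tr[[length(tr) + 1L]] <- data.frame(
          allele_id = aid, embryo_id = eid, guide_id = gid,
          true_category = switch(cat_a, NHEJ_INS = "NHEJ", NHEJ_DEL = "NHEJ",
                                 MMEJ_DEL = "MMEJ", cat_a),
          true_mh_length = true_mh, stringsAsFactors = FALSE)
      }
    }
  }
  alleles <- do.call(rbind, al); rownames(alleles) <- NULL
  truth <- do.call(rbind, tr); rownames(truth) <- NULL
  list(loci = loci, guides = do.call(rbind, guide_rows),
       alleles = alleles, truth = truth, config = config)
}
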