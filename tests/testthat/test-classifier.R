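fx <- toy_fixture()

test_that("insertions and single-base deletions are NHEJ", {
  ins <- classify_repair(indel_descriptor("insertion", fx$cut, ins_seq = "A"),
                         fx$loc, fx$cut)
  expect_equal(ins$category, "NHEJ")
  # single-base deletion stays NHEJ even inside a repeat (1-nt ambiguity)
  one <- classify_repair(indel_descriptor("deletion", fx$cut, fx$cut + 1),
                         fx$loc, fx$cut)
  expect_equal(one$category, "NHEJ")
  # delins counts as "insertion occurred"
  di <- classify_repair(indel_descriptor("delins", fx$cut - 2, fx$cut + 2,
                                         ins_seq = "T"),
                        fx$loc, fx$cut)
  expect_equal(di$category, "NHEJ")
})

test_that("deletions are MMEJ exactly when junction microhomology is in range", {
  loc <- locus("toy", "GGGCATCATGGG")
  mm <- classify_repair(indel_descriptor("deletion", 3, 6), loc, cut_site = 5)
  expect_equal(mm$category, "MMEJ")
  expect_equal(mm$mh_length, 3)
  expect_equal(mm$mh_sequence, "CAT")
  # microhomology-free deletion of >= 2 nt is NHEJ
  nh <- classify_repair(indel_descriptor("deletion", 3, 5),
                        locus("t", "AAACGTTT"), cut_site = 4)
  expect_equal(nh$category, "NHEJ")
  expect_equal(nh$mh_length, 0)
  # raising mh_min above the evidence demotes the call to NHEJ
  nm <- classify_repair(indel_descriptor("deletion", 3, 6), loc, 5,
                        classifier_params(mh_min = 4))
  expect_equal(nm$category, "NHEJ")
})

test_that("the programmed edit is HDR only on exact reproduction", {
  donor <- programmed_edit("substitution", fx$cut - 3, fx$cut + 3, "GAATTC")
  fxd <- toy_fixture(donor = donor)
  hdr <- classify_repair(indel_descriptor("substitution", fx$cut - 3,
                                          fx$cut + 3, "GAATTC"),
                         fxd$loc, fx$cut)
  expect_equal(hdr$category, "HDR")
  # overlapping but imperfect edit at the donor site: unattributable
  imperfect <- classify_repair(indel_descriptor("substitution", fx$cut - 3,
                                                fx$cut + 3, "GAATTA"),
                               fxd$loc, fx$cut)
  expect_equal(imperfect$category, "unattributable")
  # a substitution away from the donor site is mutagenic end joining
  sub <- classify_repair(indel_descriptor("substitution", fx$cut + 10,
                                          fx$cut + 12, "AA"),
                         fxd$loc, fx$cut)
  expect_equal(sub$category, "NHEJ")
  # without a donor the same allele is never HDR
  no_donor <- classify_repair(indel_descriptor("substitution", fx$cut - 3,
                                               fx$cut + 3, "GAATTC"),
                              fx$loc, fx$cut)
  expect_equal(no_donor$category, "NHEJ")
})

test_that("indels outside the repair window are unattributable", {
  loc <- locus("wide", paste(rep("ACGT", 60), collapse = ""))
  far <- classify_repair(indel_descriptor("insertion", 200, ins_seq = "A"),
                         loc, cut_site = 100)
  expect_equal(far$category, "unattributable")
  near <- classify_repair(indel_descriptor("insertion", 150, ins_seq = "A"),
                          loc, cut_site = 100)
  expect_equal(near$category, "NHEJ")
})

test_that("classification is invariant to the reported deletion placement", {
  set.seed(99)
  for (i in 1:60) {
    L <- 80
    s <- rand_seq(L, k = 2)
    loc <- locus("r", s)
    d <- rand_deletion(L, max_len = 10)
    placements <- oracle_placements(s, d[1], d[2])
    len <- d[2] - d[1]
    calls <- lapply(placements, function(p) {
      classify_repair(indel_descriptor("deletion", p, p + len), loc,
                      cut_site = 40)
    })
    expect_length(unique(vapply(calls, `[[`, character(1), "category")), 1)
    expect_length(unique(vapply(calls, `[[`, integer(1), "mh_length")), 1)
    expect_length(unique(vapply(calls, `[[`, integer(1), "canon_del_start")), 1)
  }
})

test_that("raising mh_min only ever moves alleles from MMEJ to NHEJ", {
  set.seed(123)
  loc <- locus("r", rand_seq(120, k = 2))
  dels <- replicate(80, rand_deletion(120, max_len = 10), simplify = FALSE)
  cat_at <- function(mh_min) {
    vapply(dels, function(d) {
      classify_repair(indel_descriptor("deletion", d[1], d[2]), loc, 60,
                      classifier_params(mh_min = mh_min))$category
    }, character(1))
  }
  prev <- cat_at(1)
  for (mm in 2:6) {
    cur <- cat_at(mm)
    expect_false(any(prev == "NHEJ" & cur == "MMEJ"))
    prev <- cur
  }
})

test_that("embryo profiles sum categories and compute efficiency", {
  alleles <- rbind(allele_row("e1", "none", freq = 40),
                   allele_row("e1", "deletion", 29, 32, freq = 50),
                   allele_row("e1", "insertion", fx$cut, ins = "A", freq = 10))
  prof <- classify_embryo(alleles, fx$loc, fx$guides)
  expect_equal(prof$f_mmej, 50)
  expect_equal(prof$f_nhej, 10)
  expect_equal(prof$f_unedited, 40)
  expect_equal(prof$efficiency, 60)

  expect_error(classify_embryo(alleles[0, ], fx$loc, fx$guides), "empty")
  bad <- rbind(allele_row("e1", "none", freq = 80),
               allele_row("e1", "none", freq = 80))
  expect_error(classify_embryo(bad, fx$loc, fx$guides), "malformed")
})

test_that("allele tables read 1-based coordinates and write repair calls", {
  tsv <- tempfile(fileext = ".tsv")
  writeLines(c(paste("embryo_id", "guide_id", "kind", "del_start", "del_end",
                     "ins_seq", "frequency_pct", sep = "\t"),
               paste("e1", "sg_toy", "deletion", 30, 32, "", 55, sep = "\t"),
               paste("e1", "sg_toy", "none", NA, NA, "", 45, sep = "\t")),
             tsv)
  # 1-based inclusive [30,32] is 0-based half-open [29,32)
  tab <- read_allele_table(tsv, one_based = TRUE)
  expect_equal(tab$del_start[1], 29)
  expect_equal(tab$del_end[1], 32)
  calls <- classify_alleles(tab, fx$loc, fx$guides)
  expect_equal(calls$category, c("MMEJ", "UNEDITED"))

  out <- tempfile(fileext = ".tsv")
  write_repair_calls(calls, out)
  back <- utils::read.delim(out)
  expect_equal(back$category, calls$category)
})
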