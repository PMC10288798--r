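mk_profiles <- function(fn, fm, fh = 0, fu = NULL, guide = "sg1") {
  fu <- if (is.null(fu)) pmax(0, 100 - fn - fm - fh) else fu
  data.frame(embryo_id = paste0("e", seq_along(fn)), guide_id = guide,
             f_nhej = fn, f_mmej = fm, f_hdr = fh, f_unedited = fu,
             f_unattributable = 0, efficiency = 100 - fu,
             stringsAsFactors = FALSE)
}

test_that("guide summaries take the ratio of per-guide mean frequencies", {
  s <- summarize_guide(mk_profiles(c(10, 20), c(30, 10)))
  expect_equal(s$mean_f_nhej, 15)
  expect_equal(s$mean_f_mmej, 20)
  expect_equal(s$ratio, 0.75)
  expect_equal(s$bias_class, "balanced")

  # a strongly MMEJ-biased guide, reported means
  s2 <- summarize_guide(mk_profiles(5.615, 72.385, fu = 22))
  expect_equal(s2$ratio, 5.615 / 72.385)
  expect_equal(s2$bias_class, "MMEJ-biased")

  # sentinel cases
  expect_equal(summarize_guide(mk_profiles(20, 0))$ratio, Inf)
  expect_equal(summarize_guide(mk_profiles(20, 0))$bias_class, "NHEJ-biased")
  expect_equal(summarize_guide(mk_profiles(0, 0, fu = 100))$bias_class,
               "undefined")
  expect_error(summarize_guide(mk_profiles(10, 20)[0, ]), "empty")
})

test_that("bias boundaries are inclusive in the balanced class", {
  p <- stats_params()
  expect_equal(summarize_guide(mk_profiles(10, 20))$bias_class, "balanced")  # 0.5
  expect_equal(summarize_guide(mk_profiles(40, 20))$bias_class, "balanced")  # 2
  expect_equal(summarize_guide(mk_profiles(41, 20))$bias_class, "NHEJ-biased")
  expect_equal(summarize_guide(mk_profiles(9.9, 20))$bias_class, "MMEJ-biased")
})

test_that("the ratio is invariant under proportional mosaicism rescaling", {
  set.seed(5)
  fn <- runif(6, 5, 30); fm <- runif(6, 5, 30)
  base <- summarize_guide(mk_profiles(fn, fm))
  scaled <- summarize_guide(mk_profiles(0.6 * fn, 0.6 * fm))
  expect_equal(scaled$ratio, base$ratio)
})

test_that("bias census counts and proportions use the classified denominator", {
  classes <- c(rep("MMEJ-biased", 18), rep("balanced", 31),
               rep("NHEJ-biased", 39))
  cen <- bias_census(classes)
  expect_equal(sum(cen$n), 88)
  expect_equal(cen$pct[cen$bias_class == "MMEJ-biased"], 20.45)
  # the balanced share among the 70 non-MMEJ-biased guides
  cen70 <- bias_census(classes[classes != "MMEJ-biased"])
  expect_equal(cen70$pct[cen70$bias_class == "balanced"], 44.29)
  # degenerate: one class only
  expect_equal(bias_census(rep("balanced", 4))$pct[2], 100)
  expect_error(bias_census(character(0)), "defined bias class")
})

test_that("efficiency strata partition the cohort at a strict threshold", {
  set.seed(8)
  summ <- data.frame(guide_id = paste0("sg", 1:88),
                     mean_efficiency = c(runif(50, 10, 66.69),
                                         runif(38, 66.7, 95)),
                     bias_class = c(rep(c("MMEJ-biased", "balanced"),
                                        c(8, 42)),
                                    rep(c("MMEJ-biased", "NHEJ-biased"),
                                        c(10, 28))),
                     stringsAsFactors = FALSE)
  st <- stratify_by_efficiency(summ)
  expect_equal(sum(st$n_guides), 88)
  expect_equal(st$n_guides, c(50, 38))
  expect_equal(st$pct_mmej_biased, c(16, 26.32))
  # moving the threshold reassigns guides monotonically
  for (t in c(30, 50, 80)) {
    st_t <- stratify_by_efficiency(summ, stats_params(eff_threshold = t))
    expect_equal(sum(st_t$n_guides), 88)
  }
  n_low <- vapply(c(30, 50, 66.7, 80),
                  function(t) stratify_by_efficiency(
                    summ, stats_params(eff_threshold = t))$n_guides[1],
                  numeric(1))
  expect_true(all(diff(n_low) >= 0))
})

test_that("positive rates reproduce simple genotyping arithmetic", {
  expect_equal(positive_rate(6, 11), 54.55)
  expect_equal(positive_rate(1, 16), 6.25)
  expect_equal(positive_rate(0, 9), 0)
  expect_error(positive_rate(1, 0), "positive")
  expect_error(positive_rate(5, 3), "positives")
})

test_that("fold change normalizes treated replicates by locus baseline means", {
  trials <- data.frame(
    locus_id = c("A", "A", "A", "B", "B"),
    arm = c("baseline", "baseline", "treated", "baseline", "treated"),
    efficiency = c(18, 22, 48, 0, 30))
  fc <- hdr_fold_change(trials)
  expect_equal(fc$folds$fold, 2.4)          # 48 / mean(18, 22)
  expect_equal(fc$excluded_loci, "B")       # zero baseline mean
  # all-equal arms give overall fold 1
  eq <- data.frame(locus_id = rep(c("A", "B"), each = 2),
                   arm = rep(c("baseline", "treated"), 2),
                   efficiency = c(20, 20, 35, 35))
  expect_equal(hdr_fold_change(eq)$overall_fold, 1)
  expect_error(hdr_fold_change(trials[trials$arm == "baseline", ]),
               "no valid")
})

test_that("category means recovered from simulation sharpen with cohort size", {
  w <- c(UNEDITED = 0.3, NHEJ_INS = 0.1, NHEJ_DEL = 0.2, MMEJ_DEL = 0.4,
         HDR = 0)
  mae <- function(n_embryos, seed) {
    cfg <- simulation_config(seed = seed, n_guides = 12, n_embryos = n_embryos,
                             category_weights = w, locus_length = 200)
    sim <- simulate_cohort(cfg)
    summ <- summarize_guides(embryo_profiles(
      classify_alleles(sim$alleles, sim$loci, sim$guides)))
    mean(abs(summ$mean_f_nhej - 30) + abs(summ$mean_f_mmej - 40))
  }
  expect_lt(mae(100, seed = 21), mae(10, seed = 21))
})
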