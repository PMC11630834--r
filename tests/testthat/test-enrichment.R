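test_that("running_sum evaluates the weighted statistic exactly", {
  prof <- metric_profile(c(1, -3))
  expect_equal(running_sum(prof, 1), c(1, 0))

  prof2 <- metric_profile(c(2, 1, 0, -5))
  expect_equal(running_sum(prof2, 4), c(-1/3, -2/3, -1, 0))

  # all members packed at the top: RS reaches exactly +1 at rank N_h
  set.seed(5)
  prof3 <- metric_profile(sort(rnorm(12), decreasing = TRUE))
  rs <- running_sum(prof3, 1:4)
  expect_equal(rs[4], 1)
  expect_true(all(abs(rs) <= 1 + 1e-12))
})

test_that("running_sum rejects degenerate member sets", {
  prof <- metric_profile(c(3, 2, 1, -1))
  expect_error(running_sum(prof, integer(0)), "1 <= N_h")
  expect_error(running_sum(prof, 1:4), "1 <= N_h")
  expect_error(running_sum(prof, c(1, 1)), "distinct")
  expect_error(running_sum(prof, 9), "1..N")
  prof0 <- metric_profile(c(1, 0, -1))
  expect_error(running_sum(prof0, 2), "N_R = 0")
})

test_that("enrichment_score takes the first maximal deviation, signed", {
  expect_equal(enrichment_score(c(1, 0)), 1)
  expect_equal(enrichment_score(c(-1/3, -2/3, -1, 0)), -1)
  expect_equal(enrichment_score(c(0.5, -0.5)), 0.5)   # first index wins ties
  expect_equal(enrichment_score(c(-0.5, 0.5)), -0.5)
  expect_error(enrichment_score(numeric(0)), "empty")
})

test_that("pipeline ES equals the term-by-term oracle and fgsea", {
  library(fgsea)
  set.seed(13)
  for (N in c(6, 25, 80)) {
    r <- sort(rnorm(N), decreasing = TRUE)
    prof <- metric_profile(r, seed = N)
    for (rep in 1:20) {
      members <- sort(sample(N, sample(N - 1, 1)))
      es <- enrichment_score(running_sum(prof, members))
      expect_equal(es, oracle_es(r, members), tolerance = 1e-12)
      expect_equal(es,
                   fgsea::calcGseaStat(r, selectedStats = members,
                                       gseaParam = 1),
                   tolerance = 1e-12)
    }
  }
})

test_that("vectorized null ES agrees with the naive path", {
  set.seed(17)
  for (rep in 1:30) {
    N <- sample(10:60, 1)
    r <- sort(rnorm(N), decreasing = TRUE)
    n_h <- sample(N - 1, 1)
    idx <- matrix(sort(sample(N, n_h)), ncol = 1)
    fast <- kinactive:::.es_for_member_sets(abs(r), idx)
    expect_equal(fast, oracle_es(r, idx[, 1]), tolerance = 1e-12)
  }
})

test_that("permutation null is reproducible and matches exhaustive support", {
  prof <- metric_profile(c(2.5, 0.7, -1.9), seed = 23)
  support <- vapply(1:3, function(i)
    enrichment_score(running_sum(prof, i)), 0)
  null <- permutation_null(prof, n_h = 1, n_permutations = 3000, seed = 9)
  expect_length(null, 3000)
  expect_true(all(vapply(null, function(e)
    any(abs(e - support) < 1e-12), NA)))
  expect_true(all(abs(null) <= 1 + 1e-12))
  # identical seeds give identical null collections
  expect_identical(null, permutation_null(prof, 1, 3000, seed = 9))
  expect_false(identical(null, permutation_null(prof, 1, 3000, seed = 10)))
  # the caller's RNG stream is not consumed
  set.seed(1); before <- rnorm(1)
  set.seed(1); invisible(permutation_null(prof, 1, 10, seed = 3))
  expect_identical(rnorm(1), before)
})

test_that("empirical p-values are two-sided on magnitude with a floor", {
  expect_equal(empirical_p(0, rnorm(100)), 1)
  expect_equal(empirical_p(0.9, runif(1000, 0, 0.5)), 1/1000)  # floor
  expect_equal(empirical_p(0.5, c(0.5, -0.5, 0.1, 0.2)), 0.5)
  expect_error(empirical_p(0.5, numeric(0)), "empty")
})

test_that("bonferroni_q multiplies and clamps", {
  expect_equal(bonferroni_q(0.0001, 381), 0.0381)
  expect_equal(bonferroni_q(0.5, 10), 1)
  expect_equal(bonferroni_q(0.123, 1), 0.123)
})

test_that("activity score is signed, capped -log10(p)", {
  expect_equal(activity_score(0.01, -0.4, 1000), -2)
  expect_equal(activity_score(1/1000, 0.4, 1000), 3)   # cap attained
  expect_equal(activity_score(1, 0.4, 1000), 0)
  expect_equal(activity_score(1, -0.4, 1000), 0)
  expect_equal(activity_score(0.05, 0, 1000), 0)        # es = 0
  expect_true(abs(activity_score(1e-9, 1, 100)) <= log10(100))
})

make_inference_fixture <- function(seed = 101, k_serthr = 4, k_tyr = 2,
                                   n_pep = 120) {
  pssms <- make_pssm_set(k_serthr, k_tyr, seed = seed)
  bg <- make_background(600, seed = seed)
  tables <- compute_quantile_tables(pssms, bg)
  ex <- make_experiment(pssms, tables,
                        data.frame(kinase = names(pssms)[1],
                                   direction = "up"),
                        n_peptides = n_pep, effect_size = 8, noise_sd = 1,
                        seed = seed)
  list(pssms = pssms, tables = tables, ex = ex)
}

test_that("infer_activities recovers direction and applies Bonferroni", {
  fx <- make_inference_fixture()
  planted <- fx$ex$truth$kinase[1]
  res <- infer_activities(fx$ex$profile, fx$pssms, fx$tables, n_top = 3,
                          n_permutations = 500, seed = 7)
  expect_equal(sort(res$kinase), sort(names(fx$pssms)))
  row <- res[res$kinase == planted, ]
  expect_gt(row$es, 0)
  expect_gt(row$activity, 0)
  k_tested <- attr(res, "k_tested")
  tested <- res$reason == ""
  expect_equal(res$q_value[tested],
               pmin(1, res$p_value[tested] * k_tested))
  expect_true(all(abs(res$activity) <= log10(500) + 1e-12))
  expect_true(all(sign(res$activity[res$es != 0 & tested]) ==
                  sign(res$es[res$es != 0 & tested])))
  expect_true(all(diff(res$activity) <= 0))  # sorted by activity, descending
})

test_that("single-kinase runs give q equal to p", {
  fx <- make_inference_fixture(seed = 111, k_serthr = 1, k_tyr = 0)
  res <- infer_activities(fx$ex$profile, fx$pssms, fx$tables, n_top = 1,
                          n_permutations = 100, seed = 2)
  expect_equal(res$q_value, res$p_value)
})

test_that("degenerate kinases are reported with reason codes, not dropped", {
  pssms <- make_pssm_set(2, 1, seed = 121)
  bg <- make_background(400, seed = 121)
  tables <- compute_quantile_tables(pssms, bg)
  # profile without any Tyr-centred peptide: the Tyr kinase has no substrate
  peps <- make_background(80, seed = 122)
  keep <- substr(peps, 6, 6) != "Y"
  set.seed(3)
  prof <- ranked_profile(peps[keep], rnorm(sum(keep)))
  res <- infer_activities(prof, pssms, tables, n_top = 1,
                          n_permutations = 200, seed = 1)
  tyr <- res[res$kinase == "TYR001", ]
  expect_equal(tyr$reason, "no_substrates")
  expect_equal(tyr$es, 0)
  expect_equal(tyr$p_value, 1)
  expect_equal(tyr$activity, 0)
  expect_equal(attr(res, "k_tested"), 2)
  expect_equal(res$q_value[res$reason == ""],
               pmin(1, res$p_value[res$reason == ""] * 2))
})

test_that("inference is deterministic and scale-invariant in the metric", {
  fx <- make_inference_fixture(seed = 131)
  run <- function(prof) infer_activities(prof, fx$pssms, fx$tables,
                                         n_top = 3, n_permutations = 300,
                                         seed = 11)
  res1 <- run(fx$ex$profile)
  res2 <- run(fx$ex$profile)
  f1 <- tempfile(); f2 <- tempfile()
  write_kinase_results(res1, f1); write_kinase_results(res2, f2)
  expect_identical(readLines(f1), readLines(f2))  # byte-identical reruns

  prof3 <- ranked_profile(fx$ex$profile$peptide, 3 * fx$ex$profile$metric)
  res3 <- run(prof3)
  expect_identical(res3$kinase, res1$kinase)
  expect_equal(res3$es, res1$es, tolerance = 1e-12)
  expect_identical(res3$p_value, res1$p_value)
  expect_equal(res3$activity, res1$activity, tolerance = 1e-12)
})

test_that("result tables survive the TSV round trip", {
  fx <- make_inference_fixture(seed = 141)
  res <- infer_activities(fx$ex$profile, fx$pssms, fx$tables, n_top = 3,
                          n_permutations = 100, seed = 5)
  f <- tempfile(fileext = ".tsv")
  write_kinase_results(res, f)
  back <- read_kinase_results(f)
  expect_equal(back$kinase, res$kinase)
  expect_equal(back$activity, res$activity, tolerance = 1e-5)  # 6 sig. digits
  expect_error(read_kinase_results(tempfile()), "not found")
})
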