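test_that("expected offspring distributions match the printed crosses", {
  # one-copy sire x one-pseudocopy dam: 50/50 in each sex
  d1 <- offspring_distribution(0, 1)
  expect_equal(dplyr::filter(d1, sex == "F")$prob, c(0.25, 0.25))
  expect_equal(dplyr::filter(d1, sex == "F")$total_copies, c(0L, 1L))
  expect_equal(dplyr::filter(d1, sex == "M")$total_copies, c(1L, 2L))
  # two-copy sire x one-copy dam: 25/50/25 in each sex
  d2 <- offspring_distribution(1, 1)
  f2 <- dplyr::filter(d2, sex == "F")
  expect_equal(f2$prob / sum(f2$prob), c(0.25, 0.5, 0.25))
  expect_equal(f2$total_copies, 0:2)
  # trivial crosses
  d0 <- offspring_distribution(0, 0)
  expect_equal(d0$total_copies, c(0L, 1L))
  expect_equal(d0$prob, c(0.5, 0.5))
  d3 <- offspring_distribution(2, 2)
  expect_equal(dplyr::filter(d3, sex == "F")$total_copies, 2L)
  expect_equal(dplyr::filter(d3, sex == "M")$total_copies, 3L)
})

test_that("model equals the gamete-enumeration oracle for all nine configs", {
  for (s in 0:2) for (d in 0:2) {
    got <- offspring_distribution(s, d) |> as.data.frame()
    want <- oracle_offspring_distribution(s, d) |> as.data.frame()
    expect_equal(got, want, info = sprintf("config (%d,%d)", s, d))
    expect_equal(sum(got$prob), 1)
  }
  # YY super-male extension: all offspring male
  yy <- offspring_distribution(0, 0, sire_y = 2)
  expect_true(all(yy$sex == "M"))
  expect_equal(as.data.frame(yy),
               as.data.frame(oracle_offspring_distribution(0, 0, sire_y = 2)))
})

test_that("daughter copy distribution equals the son distribution shifted by one", {
  for (s in 0:2) for (d in 0:2) {
    dist <- offspring_distribution(s, d)
    f <- dplyr::filter(dist, sex == "F")
    m <- dplyr::filter(dist, sex == "M")
    expect_equal(f$prob, m$prob)
    expect_equal(f$total_copies + 1L, m$total_copies)
  }
})

test_that("discordance classes follow phenotype and copy number", {
  calls <- tibble::tibble(
    sample = paste0("s", 1:7),
    copies = c(1L, 1L, 3L, 0L, 2L, NA, 1L),
    status = c("ok", "ok", "ok", "ok", "ok", "ambiguous", "ok")
  )
  ped <- tibble::tibble(id = paste0("s", 1:7),
                        phenotypic_sex = c("F", "M", "M", "F", "F", "M", "U"))
  cls <- classify_discordance(calls, ped)
  expect_equal(cls$class,
               c("discordant_female", "concordant", "carrier_male",
                 "concordant", "discordant_female", "unknown", "unknown"))
})

test_that("parental configuration inference recovers clear patterns", {
  # all daughters zero copies, all sons one: (0,0) strictly best from n >= 5
  counts <- tibble::tibble(sex = c("F", "M"), copies = c(0L, 1L), n = c(5L, 5L))
  fit <- infer_parental_config(counts)
  expect_false(fit$tie)
  expect_equal(fit$best$sire_auto, 0L)
  expect_equal(fit$best$dam_auto, 0L)
  expect_equal(glance(fit)$status, "ok")
  expect_equal(nrow(tidy(fit)), 9)

  # a 50/50 pattern cannot tell (0,1) from (1,0) without parent calls
  counts2 <- tibble::tibble(sex = rep(c("F", "M"), each = 2),
                            copies = c(0L, 1L, 1L, 2L), n = c(20L, 20L, 20L, 20L))
  fit2 <- infer_parental_config(counts2)
  expect_true(fit2$tie)
  expect_setequal(paste(fit2$best$sire_auto, fit2$best$dam_auto),
                  c("0 1", "1 0"))
  fit3 <- infer_parental_config(counts2, sire_call = 0L, dam_call = 1L)
  expect_false(fit3$tie)
  expect_equal(fit3$best$dam_auto, 1L)

  # no usable offspring
  empty <- infer_parental_config(tibble::tibble(sex = character(),
                                                copies = integer()))
  expect_equal(empty$status, "no_information")
})

test_that("parental configuration is recovered on simulated 20-offspring families", {
  n_rep <- 120
  hits <- withr::with_seed(77, vapply(seq_len(n_rep), function(i) {
    s <- sample(0:2, 1)
    d <- sample(0:2, 1)
    probs <- offspring_distribution(s, d)
    draw <- sample(seq_len(nrow(probs)), 20, replace = TRUE, prob = probs$prob)
    counts <- probs[draw, c("sex", "total_copies")] |>
      dplyr::count(sex, total_copies, name = "n") |>
      dplyr::rename(copies = total_copies)
    fit <- infer_parental_config(counts)
    any(fit$best$sire_auto == s & fit$best$dam_auto == d)
  }, logical(1)))
  expect_gte(mean(hits), 0.95)
})

test_that("Monte-Carlo goodness of fit matches exact enumeration", {
  perfect <- gof_test(c(20, 20), c(0.5, 0.5), replicates = 1000, seed = 1)
  expect_equal(perfect$statistic, 0)
  expect_equal(perfect$p_mc, 1)

  g <- gof_test(c(30, 10), c(0.5, 0.5), replicates = 1e4, seed = 3)
  expect_equal(g$statistic, 10)
  p_exact <- oracle_exact_gof_p(c(30, 10))
  se <- sqrt(p_exact * (1 - p_exact) / 1e4)
  expect_lt(abs(g$p_mc - p_exact), 3 * se)
  expect_gte(g$p_mc, 1 / (1e4 + 1))
})

test_that("goodness of fit handles degenerate categories", {
  # zero-expectation category with observations: impossible flag and floor p
  g <- gof_test(c(5, 5), c(1, 0), replicates = 1000, seed = 2)
  expect_true(g$impossible)
  expect_equal(g$p_mc, 1 / 1001)
  # zero-expectation, zero-observation categories are dropped
  g2 <- gof_test(c(10, 10, 0), c(0.5, 0.5, 0), replicates = 1000, seed = 2)
  expect_false(g2$impossible)
  expect_equal(g2$statistic, 0)
  # no observations at all
  g3 <- gof_test(c(0, 0), c(0.5, 0.5), replicates = 1000, seed = 2)
  expect_equal(g3$status, "no_information")
  expect_error(gof_test(c(1, 1), c(0.6, 0.6)), "sum to 1")
})

test_that("Monte-Carlo p-values are uniform under the null model", {
  probs <- offspring_distribution(1, 1) |> dplyr::filter(sex == "F")
  p <- probs$prob / sum(probs$prob)
  pvals <- withr::with_seed(55, vapply(seq_len(400), function(i) {
    obs <- as.vector(rmultinom(1, 40, p))
    gof_test(obs, p, replicates = 1500, seed = i)$p_mc
  }, numeric(1)))
  ks <- suppressWarnings(stats::ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 1e-3)
})

test_that("gof tidiers expose the per-category table and summary", {
  g <- gof_test(c(30, 10), c(0.5, 0.5), replicates = 1000, seed = 4)
  td <- tidy(g)
  expect_equal(td$expected, c(20, 20))
  expect_equal(sum(td$contribution), g$statistic)
  gl <- glance(g)
  expect_equal(gl$statistic, g$statistic)
  expect_equal(gl$seed, 4)
})
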