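#' Expected offspring (sex x sdY copy number) distribution for a cross
#'
#' Core Mendelian model: the sdY pseudocopy is a single biallelic autosomal
#' locus, so each parent transmits a pseudocopy allele independently with
#' probability `auto_alleles / 2`; offspring sex is determined by the sire's
#' Y-linked sdY copy independently of pseudocopy transmission. An
#' offspring's total copy number is its pseudocopy allele count plus one if
#' male. A YY super-male sire (`sire_y = 2`) is supported as an extension
#' and produces all-male offspring.
#'
#' @param sire_auto,dam_auto Parental pseudocopy allele counts (0, 1 or 2).
#' @param sire_y Y-linked copies of the sire (1 = XY, 2 = YY); the dam has
#'   none.
#' @return Tibble (`sex`, `total_copies`, `prob`) over the classes with
#'   positive probability; probabilities sum to 1.
#' @examples
#' offspring_distribution(0, 1)  # 50/50 zero- vs one-copy daughters
#' offspring_distribution(1, 1)  # 25/50/25 over 0/1/2-copy daughters
#' @export
offspring_distribution <- function(sire_auto, dam_auto, sire_y = 1) {
  stopifnot(length(sire_auto) == 1, length(dam_auto) == 1,
            sire_auto %in% 0:2, dam_auto %in% 0:2, sire_y %in% 1:2)
  ps <- sire_auto / 2
  pd <- dam_auto / 2
  p_auto <- c(
    `0` = (1 - ps) * (1 - pd),
    `1` = ps * (1 - pd) + (1 - ps) * pd,
    `2` = ps * pd
  )
  p_male <- if (sire_y == 2) 1 else 0.5
  crossing(sex = c("F", "M"), auto = 0:2) %>%
    mutate(
      prob = ifelse(.data$sex == "M", p_male, 1 - p_male) *
        unname(p_auto[as.character(.data$auto)]),
      total_copies = .data$auto + as.integer(.data$sex == "M")
    ) %>%
    filter(.data$prob > 0) %>%
    select("sex", "total_copies", "prob") %>%
    arrange(.data$sex, .data$total_copies)
}

#' Classify phenotype/genotype concordance from copy-number calls
#'
#' A phenotypic female with one or more sdY copies is a discordant female
#' (she carries pseudocopies but no Y); a phenotypic male with two or more
#' copies is a carrier male (Y-linked copy plus pseudocopies). Zero-copy
#' females and one-copy males are concordant. Unrecorded sex or a
#' non-definite call yields `unknown`.
#'
#' @param calls Copy-number calls ([call_copy_number()] output or any tibble
#'   with `sample`, `copies`, and optionally `status`).
#' @param pedigree Tibble with `id` and `phenotypic_sex` (`M`/`F`/`U`).
#' @return The calls joined to the pedigree with a `class` column in
#'   `concordant` / `discordant_female` / `carrier_male` / `unknown`.
#' @export
classify_discordance <- function(calls, pedigree) {
  stopifnot(all(c("sample", "copies") %in% names(calls)),
            all(c("id", "phenotypic_sex") %in% names(pedigree)))
  if (!"status" %in% names(calls)) calls$status <- "ok"
  calls %>%
    inner_join(select(pedigree, sample = "id", "phenotypic_sex",
                      any_of("family")),
               by = "sample") %>%
    mutate(class = case_when(
      .data$status != "ok" | is.na(.data$copies) ~ "unknown",
      !(.data$phenotypic_sex %in% c("M", "F")) ~ "unknown",
      .data$phenotypic_sex == "F" & .data$copies >= 1 ~ "discordant_female",
      .data$phenotypic_sex == "M" & .data$copies >= 2 ~ "carrier_male",
      TRUE ~ "concordant"
    ))
}

#' Infer the parental pseudocopy configuration from offspring counts
#'
#' Computes the multinomial log-likelihood of the observed offspring
#' (sex, copies) counts under [offspring_distribution()] for each of the
#' nine (sire, dam) pseudocopy configurations and returns the best fit with
#' the full likelihood table. Configurations that differ only by swapping
#' sire and dam pseudocopy counts are indistinguishable from offspring data
#' alone; such ties are resolved only when parental copy-number calls are
#' supplied, never arbitrarily.
#'
#' @param counts Tibble of offspring with columns `sex` (`M`/`F`) and
#'   `copies` (total sdY copies), optionally pre-aggregated with a count
#'   column `n`.
#' @param sire_call,dam_call Optional parental pseudocopy allele counts from
#'   qPCR calls (sire pseudocopies = sire total copies - 1; dam pseudocopies
#'   = dam total copies), used only to resolve likelihood ties.
#' @return Object of class `sdy_parental_fit`: fields `table` (all nine
#'   configurations with log-likelihoods), `best` (rows attaining the
#'   maximum after tie resolution), `tie` and `status`. [tidy()] returns the
#'   table, [glance()] a one-row summary.
#' @export
infer_parental_config <- function(counts, sire_call = NULL, dam_call = NULL) {
  stopifnot(all(c("sex", "copies") %in% names(counts)))
  if (!"n" %in% names(counts)) {
    counts <- count(counts, .data$sex, .data$copies, name = "n")
  }
  counts <- filter(counts, .data$n > 0, !is.na(.data$copies),
                   .data$sex %in% c("M", "F"))
  configs <- crossing(sire_auto = 0:2, dam_auto = 0:2)
  if (nrow(counts) == 0 || sum(counts$n) == 0) {
    return(structure(list(table = mutate(configs, loglik = NA_real_),
                          best = configs[0, ], tie = FALSE,
                          status = "no_information"),
                     class = "sdy_parental_fit"))
  }
  tab <- configs %>%
    mutate(loglik = pmap(list(.data$sire_auto, .data$dam_auto),
                         function(s, d) {
      probs <- offspring_distribution(s, d)
      joined <- left_join(counts, probs, by = c("sex", "copies" = "total_copies"))
      if (any(is.na(joined$prob))) -Inf else sum(joined$n * log(joined$prob))
    })) %>%
    mutate(loglik = unlist(.data$loglik))
  best_ll <- max(tab$loglik)
  best <- filter(tab, .data$loglik >= best_ll - 1e-9)
  tie <- nrow(best) > 1
  if (tie && (!is.null(sire_call) || !is.null(dam_call))) {
    keep <- rep(TRUE, nrow(best))
    if (!is.null(sire_call)) keep <- keep & best$sire_auto == sire_call
    if (!is.null(dam_call)) keep <- keep & best$dam_auto == dam_call
    if (any(keep)) best <- best[keep, ]
  }
  structure(list(table = tab, best = best, tie = nrow(best) > 1,
                 status = "ok", n = sum(counts$n)),
            class = "sdy_parental_fit")
}

#' @export
print.sdy_parental_fit <- function(x, ...) {
  cat("<sdy_parental_fit>", x$status, "\n")
  if (x$status == "ok") {
    cat(sprintf("  best (sire_auto, dam_auto): %s%s\n",
                paste(sprintf("(%d,%d)", x$best$sire_auto, x$best$dam_auto),
                      collapse = " "),
                if (x$tie) " [tie]" else ""))
  }
  invisible(x)
}

#' @rdname infer_parental_config
#' @param x An `sdy_parental_fit` object.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.sdy_parental_fit <- function(x, ...) arrange(x$table, -.data$loglik)

#' @rdname infer_parental_config
#' @exportS3Method generics::glance
glance.sdy_parental_fit <- function(x, ...) {
  if (x$status != "ok") {
    return(tibble(sire_auto = NA_integer_, dam_auto = NA_integer_,
                  loglik = NA_real_, tie = FALSE, status = x$status))
  }
  tibble(sire_auto = x$best$sire_auto[1], dam_auto = x$best$dam_auto[1],
         loglik = x$best$loglik[1], tie = x$tie, status = x$status)
}

#' Monte-Carlo chi-squared goodness-of-fit test
#'
#' Pearson's X2 of observed category counts against model-expected
#' probabilities, with the p-value computed by Monte-Carlo simulation of
#' multinomial samples under the model:
#' `p = (1 + #\{simulated X2 >= observed X2\}) / (1 + replicates)`.
#' Categories with zero expectation and zero observation are dropped; a
#' zero-expectation category with observations makes the configuration
#' impossible and the floor p-value `1/(replicates + 1)` is reported with a
#' flag.
#'
#' @param observed Vector of non-negative integer counts (optionally named).
#' @param expected Vector of expected probabilities, same length, summing
#'   to 1.
#' @param replicates Number of Monte-Carlo replicates (the conventional
#'   default is 1e6; tests and pipelines may use fewer).
#' @param seed Seed for the Monte-Carlo draw (recorded in the result).
#' @return Object of class `sdy_gof` with fields `statistic`, `p_mc`,
#'   `replicates`, `seed`, `impossible`, `n`, `observed`, `expected`.
#'   [tidy()] gives the per-category table, [glance()] a one-row summary.
#' @examples
#' gof_test(c(30, 10), c(0.5, 0.5), replicates = 1e4, seed = 1)
#' @export
gof_test <- function(observed, expected, replicates = 1e6, seed = 1) {
  stopifnot(length(observed) == length(expected), all(observed >= 0),
            all(expected >= 0), replicates >= 1)
  if (abs(sum(expected) - 1) > 1e-8) {
    abort("expected probabilities must sum to 1")
  }
  categories <- names(observed) %||% as.character(seq_along(observed))
  n <- sum(observed)
  if (n == 0) {
    return(structure(list(statistic = NA_real_, p_mc = NA_real_,
                          replicates = replicates, seed = seed,
                          impossible = FALSE, n = 0,
                          observed = observed, expected = expected,
                          categories = categories, status = "no_information"),
                     class = "sdy_gof"))
  }
  keep <- !(expected == 0 & observed == 0)
  obs <- observed[keep]
  exp_p <- expected[keep]
  categories <- categories[keep]
  impossible <- any(exp_p == 0 & obs > 0)
  if (impossible) {
    return(structure(list(statistic = Inf, p_mc = 1 / (replicates + 1),
                          replicates = replicates, seed = seed,
                          impossible = TRUE, n = n, observed = obs,
                          expected = exp_p, categories = categories,
                          status = "ok"),
                     class = "sdy_gof"))
  }
  exp_n <- n * exp_p
  stat <- sum((obs - exp_n)^2 / exp_n)
  withr::local_seed(seed)
  n_ge <- 0
  left <- replicates
  while (left > 0) {
    m <- min(left, 1e5)
    sim <- rmultinom(m, n, exp_p)
    sim_stat <- colSums((sim - exp_n)^2 / exp_n)
    n_ge <- n_ge + sum(sim_stat >= stat - 1e-9)
    left <- left - m
  }
  structure(list(statistic = stat, p_mc = (1 + n_ge) / (1 + replicates),
                 replicates = replicates, seed = seed, impossible = FALSE,
                 n = n, observed = obs, expected = exp_p,
                 categories = categories, status = "ok"),
            class = "sdy_gof")
}

#' @export
print.sdy_gof <- function(x, ...) {
  cat("<sdy_gof>")
  if (!is.null(x$status) && x$status == "no_information") {
    cat(" no information (n = 0)\n")
    return(invisible(x))
  }
  cat(sprintf(" X2 = %.4g, Monte-Carlo p = %.4g (%g replicates, seed %s)%s\n",
              x$statistic, x$p_mc, x$replicates, x$seed,
              if (x$impossible) " [impossible category]" else ""))
  invisible(x)
}

#' @rdname gof_test
#' @param x An `sdy_gof` object.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.sdy_gof <- function(x, ...) {
  if (x$n == 0) return(tibble())
  tibble(
    category = x$categories, observed = as.numeric(x$observed),
    expected = x$n * x$expected,
    contribution = ifelse(x$expected > 0,
                          (x$observed - x$n * x$expected)^2 /
                            (x$n * x$expected), Inf)
  )
}

#' @rdname gof_test
#' @exportS3Method generics::glance
glance.sdy_gof <- function(x, ...) {
  tibble(statistic = x$statistic, p_mc = x$p_mc, n = x$n,
         replicates = x$replicates, impossible = x$impossible,
         seed = x$seed)
}
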