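make_scores_clin <- function(n, score_fun, hazard_fun, seed = 1,
                             censor_rate = 0.004) {
  withr::with_seed(seed, {
    sc <- score_fun(n)
    s <- sim_surv(n, hazard_fun(sc), censor_rate = censor_rate)
  })
  ids <- sprintf("S%04d", seq_len(n))
  list(scores = risk_scores(ids, sc),
       clin = clinical_table(data.frame(sample_id = ids,
                                        time_months = s$time,
                                        event = s$event,
                                        stringsAsFactors = FALSE)))
}

test_that("prognostic index is the beta-weighted sum of expression rows", {
  z <- toy_expression()
  sig <- gene_signature(c("GA", "GB"))
  zero <- prognostic_index(c(GA = 0, GB = 0), z, sig)
  expect_true(all(zero$score == 0))

  one <- prognostic_index(c(GA = 1), z, gene_signature("GA"))
  expect_equal(one$score, unname(z$values["GA", ]))

  # equal rows with opposite coefficients cancel
  vals <- z$values
  vals["GB", ] <- vals["GA", ]
  z2 <- expression_matrix(vals, z$is_reference)
  cancel <- prognostic_index(c(GA = 1, GB = -1), z2, sig)
  expect_true(all(cancel$score == 0))

  expect_error(prognostic_index(c(GA = 1), z, sig), "missing beta")
  expect_error(prognostic_index(c(GX = 1), z, gene_signature("GX")),
               "not in expression")
})

test_that("metagene score is the unweighted mean and is order invariant", {
  z <- toy_expression()
  single <- metagene_score(z, gene_signature("GB"))
  expect_equal(single$score, unname(z$values["GB", ]))

  vals <- z$values
  vals["GB", ] <- -vals["GA", ]
  z2 <- expression_matrix(vals, z$is_reference)
  opp <- metagene_score(z2, gene_signature(c("GA", "GB")))
  expect_true(all(abs(opp$score) < 1e-12))

  fwd <- metagene_score(z, gene_signature(c("GA", "GC")))
  rev <- metagene_score(z, gene_signature(c("GC", "GA")))
  expect_equal(fwd$score, rev$score)
})

test_that("maximized 2-group split beats the median split and matches brute force", {
  dat <- make_scores_clin(30, function(n) rnorm(n),
                          function(sc) 0.02 * exp(0.5 * sc), seed = 8)
  part <- maximize_risk_groups(dat$scores, dat$clin, n_groups = 2,
                               min_frac = 0.1)
  expect_s3_class(part, "RiskPartition")
  expect_lte(part$logrank$p, part$median_split$p)

  # independent brute force over every feasible cut via the O/E/V oracle
  s <- dat$scores$score
  idx <- match(dat$scores$sample_id, dat$clin$sample_id)
  time <- dat$clin$time_months[idx]; event <- dat$clin$event[idx]
  u <- sort(unique(s)); cuts <- (u[-1] + u[-length(u)]) / 2
  best_p <- Inf; best_cut <- NA
  for (c1 in cuts) {
    g <- s > c1
    if (sum(g) < 3 || sum(!g) < 3) next
    stat <- oracle_logrank2(time, event, g)$statistic
    p <- pchisq(stat, 1, lower.tail = FALSE)
    if (p < best_p) { best_p <- p; best_cut <- c1 }
  }
  expect_equal(part$cutpoints, best_cut)
  expect_equal(part$logrank$p, best_p, tolerance = 1e-10)
})

test_that("maximized p-value is non-increasing as min_frac decreases", {
  dat <- make_scores_clin(80, function(n) rnorm(n),
                          function(sc) 0.02 * exp(0.4 * sc), seed = 12)
  p_wide <- maximize_risk_groups(dat$scores, dat$clin, 2, 0.05)$logrank$p
  p_mid <- maximize_risk_groups(dat$scores, dat$clin, 2, 0.2)$logrank$p
  p_tight <- maximize_risk_groups(dat$scores, dat$clin, 2, 0.4)$logrank$p
  expect_lte(p_wide, p_mid)
  expect_lte(p_mid, p_tight)
})

test_that("maximized 3-group split orders groups by score and validates constraints", {
  dat <- make_scores_clin(60, function(n) rnorm(n),
                          function(sc) 0.02 * exp(0.6 * sc), seed = 3)
  part <- maximize_risk_groups(dat$scores, dat$clin, n_groups = 3,
                               min_frac = 0.15)
  expect_identical(levels(part$group), c("low", "medium", "high"))
  expect_length(part$cutpoints, 2L)
  ag <- tapply(dat$scores$score, part$group, mean)
  expect_true(ag["low"] < ag["medium"] && ag["medium"] < ag["high"])
  expect_true(all(part$n_per_group >= 0.15 * 60))

  expect_error(maximize_risk_groups(dat$scores, dat$clin, 3, 0.4),
               "infeasible")
  small <- make_scores_clin(10, function(n) rnorm(n),
                            function(sc) 0.05 * exp(0 * sc), seed = 4)
  expect_error(maximize_risk_groups(small$scores, small$clin, 2, 0.1),
               "min_frac")
})

test_that("quantile splits count samples as documented", {
  ids <- paste0("S", 1:8)
  scores <- risk_scores(ids, 1:8)
  q <- quantile_split(scores, mode = "quartile")
  expect_identical(names(q$group)[!is.na(q$group) & q$group == "low"],
                   c("S1", "S2"))
  expect_identical(names(q$group)[!is.na(q$group) & q$group == "high"],
                   c("S7", "S8"))
  expect_identical(q$n_excluded, 4L)

  m <- quantile_split(scores, mode = "median")
  expect_identical(as.vector(table(m$group)), c(4L, 4L))

  t3 <- quantile_split(scores, mode = "tertile")
  expect_identical(sum(is.na(t3$group)), 2L)

  expect_error(quantile_split(risk_scores(ids, rep(1, 8))), "tied")
  expect_error(quantile_split(risk_scores(ids[1:3], 1:3)), "at least 4")
})

test_that("best-cutoff scan reports BH-adjusted p for the minimum-p selection", {
  dat <- make_scores_clin(60, function(n) rnorm(n),
                          function(sc) 0.02 * exp(0.5 * sc), seed = 21)
  scan <- best_cutoff_fdr(dat$scores, dat$clin)
  expect_gte(scan$selected_q, scan$selected_p)
  expect_true(all(scan$q >= scan$p))
  expect_equal(scan$selected_p, min(scan$p))
  bounds <- quantile(dat$scores$score, c(0.25, 0.75), names = FALSE)
  expect_true(all(scan$cutoffs >= bounds[1] & scan$cutoffs <= bounds[2]))

  expect_error(best_cutoff_fdr(dat$scores, dat$clin, window = c(0, 0.75)),
               "inside \\(0, 1\\)")
  few <- risk_scores(paste0("S", 1:8), c(1, 1, 1, 1, 2, 2, 2, 2))
  clin8 <- clinical_table(data.frame(sample_id = paste0("S", 1:8),
                                     time_months = 1:8,
                                     event = rep(1, 8)))
  expect_error(best_cutoff_fdr(few, clin8), "at least 3 candidate")
})

test_that("splitters depend on score ranks only", {
  dat <- make_scores_clin(50, function(n) rnorm(n),
                          function(sc) 0.02 * exp(0.5 * sc), seed = 33)
  mono <- risk_scores(dat$scores$sample_id, exp(2 * dat$scores$score) + 5)
  a <- maximize_risk_groups(dat$scores, dat$clin, 2, 0.1)
  b <- maximize_risk_groups(mono, dat$clin, 2, 0.1)
  expect_identical(as.character(a$group), as.character(b$group))
  expect_equal(a$logrank$p, b$logrank$p)
  qa <- quantile_split(dat$scores, dat$clin, "quartile")
  qb <- quantile_split(mono, dat$clin, "quartile")
  expect_identical(as.character(qa$group), as.character(qb$group))
})
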