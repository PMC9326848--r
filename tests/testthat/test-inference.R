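two_group_scores <- function(m_per_group = 10, shift = 1, sd = 0.4,
                             seed = 1) {
  set.seed(seed)
  tibble::tibble(
    u = c(rnorm(m_per_group, 0, sd), rnorm(m_per_group, shift, sd)),
    condition = rep(c("g1", "g2"), each = m_per_group)
  )
}

test_that("equal weights reduce WLS to the classical pooled t-test", {
  d <- two_group_scores()
  fit <- fit_score_model(d, "condition", model = "linear")
  tt <- t.test(u ~ condition, data = d, var.equal = TRUE)
  expect_equal(fit$beta, unname(diff(tt$estimate)), tolerance = 1e-12)
  expect_equal(abs(fit$t), abs(tt$statistic), ignore_attr = TRUE,
               tolerance = 1e-12)
  expect_equal(fit$p_raw, tt$p.value, tolerance = 1e-12)
  expect_equal(fit$df, 18)
})

test_that("globally rescaling weights changes no test statistic", {
  d <- two_group_scores(seed = 3)
  d$weight <- runif(nrow(d), 0.2, 3)
  d$subject <- rep(sprintf("s%d", 1:10), 2)
  base_lin <- fit_score_model(d, "condition", model = "linear")
  base_mix <- fit_score_model(d, "condition", subject = "subject",
                              model = "mixed")
  d7 <- d
  d7$weight <- d$weight * 7
  re_lin <- fit_score_model(d7, "condition", model = "linear")
  re_mix <- fit_score_model(d7, "condition", subject = "subject",
                            model = "mixed")
  for (col in c("beta", "se", "df", "t")) {
    expect_equal(re_lin[[col]], base_lin[[col]], tolerance = 1e-9)
    expect_equal(re_mix[[col]], base_mix[[col]], tolerance = 1e-6)
  }
  expect_equal(re_lin$p_raw, base_lin$p_raw, tolerance = 1e-9)
  # a tiny p-value amplifies relative error; compare on the log scale
  expect_equal(log(re_mix$p_raw), log(base_mix$p_raw), tolerance = 1e-4)
})

test_that("weighted fits recover a known effect more precisely", {
  # y = 0.5 x + e with Var(e) = c / n known up to the fitted surface
  set.seed(21)
  res <- replicate(300, {
    n <- sample(seq(20, 400, 20), 40, replace = TRUE)
    x <- rep(c(0, 1), each = 20)
    y <- 0.5 * x + rnorm(40, 0, sqrt(50 / n))
    d <- tibble::tibble(u = y, condition = x, weight = n / 50)
    dw <- fit_score_model(d, "condition", model = "linear")$beta
    d$weight <- NULL
    du <- fit_score_model(d, "condition", model = "linear")$beta
    c(weighted = dw, unweighted = du)
  })
  expect_lt(abs(mean(res["weighted", ]) - 0.5),
            3 * sd(res["weighted", ]) / sqrt(300))
  expect_lte(sd(res["weighted", ]), sd(res["unweighted", ]))
})

test_that("balanced intercept-dominated mixed fits hit the between-subject df", {
  # m subjects x k images, random-intercept variance >> residual variance:
  # Satterthwaite df must approach the exact between-subject df m - 2
  for (m in c(8, 14)) {
    set.seed(m)
    k <- 3
    subj <- rep(sprintf("s%02d", 1:m), each = k)
    cond <- rep(rep(c("g1", "g2"), each = m / 2), each = k)
    a <- rnorm(m, 0, 5)[rep(1:m, each = k)]
    d <- tibble::tibble(u = a + (cond == "g2") * 1 + rnorm(m * k, 0, 0.01),
                        condition = cond, subject = subj)
    # near-degenerate residual variance provokes optimizer gradient
    # warnings; the df is what is under test
    fit <- suppressWarnings(
      fit_score_model(d, "condition", subject = "subject", model = "mixed")
    )
    expect_lt(abs(fit$df - (m - 2)), 0.1)
    expect_gt(fit$df, 0)
    expect_lte(fit$df, fit$n_used - 2)
  }
})

test_that("zero-variance one-image-per-subject mixed fits collapse to WLS", {
  set.seed(8)
  n <- 24
  d <- tibble::tibble(
    u = rnorm(n) + rep(c(0, 1), each = n / 2),
    condition = rep(c("g1", "g2"), each = n / 2),
    subject = sprintf("s%02d", 1:n),
    weight = 1
  )
  lin <- fit_score_model(d, "condition", model = "linear")
  mix <- suppressWarnings(
    fit_score_model(d, "condition", subject = "subject", model = "mixed")
  )
  expect_equal(mix$beta, lin$beta, tolerance = 1e-6)
  expect_equal(mix$se, lin$se, tolerance = 1e-6)
  expect_equal(mix$df, lin$df, tolerance = 1e-3)
  expect_equal(mix$p_raw, lin$p_raw, tolerance = 1e-6)
})

test_that("mixed-model CIs cover a known effect and variance components", {
  set.seed(501)
  m <- 10; k <- 3; beta <- 0.5; tau <- 1; sigma <- 1
  n_rep <- 500
  cover <- logical(n_rep); tau2_hat <- sigma2_hat <- numeric(n_rep)
  subj <- rep(sprintf("s%02d", 1:m), each = k)
  cond <- rep(rep(c(0, 1), each = m / 2), each = k)
  w <- rep(runif(m * k, 0.5, 2))
  for (r in seq_len(n_rep)) {
    a <- rnorm(m, 0, tau)[rep(1:m, each = k)]
    d <- tibble::tibble(u = a + beta * cond + rnorm(m * k, 0, sigma / sqrt(w)),
                        condition = cond, subject = subj, weight = w)
    fit <- suppressWarnings(
      fit_score_model(d, "condition", subject = "subject", model = "mixed")
    )
    half <- qt(0.975, fit$df) * fit$se
    cover[r] <- abs(fit$beta - beta) <= half
    tau2_hat[r] <- fit$subject_var
    sigma2_hat[r] <- fit$residual_var
  }
  expect_gte(mean(cover), 0.92)
  expect_lte(mean(cover), 0.98)
  expect_lt(abs(mean(tau2_hat) - tau^2), 3 * sd(tau2_hat) / sqrt(n_rep))
  expect_lt(abs(mean(sigma2_hat) - sigma^2),
            3 * sd(sigma2_hat) / sqrt(n_rep))
})

test_that("swapping condition codes flips the sign and keeps the p-value", {
  d <- two_group_scores(seed = 12)
  f1 <- fit_score_model(d, "condition", model = "linear")
  f2 <- fit_score_model(d, "condition", model = "linear", reference = "g2")
  expect_equal(f2$beta, -f1$beta, tolerance = 1e-12)
  expect_equal(f2$p_raw, f1$p_raw, tolerance = 1e-12)
})

test_that("a three-level condition yields one contrast per non-reference level", {
  set.seed(30)
  d <- tibble::tibble(
    u = rnorm(45) + rep(c(0, 1, 2), each = 15),
    condition = rep(c("nonDiabetic", "onset", "longDuration"), each = 15)
  )
  fit <- fit_score_model(d, "condition", model = "linear",
                         reference = "nonDiabetic")
  expect_equal(sort(fit$term),
               sort(c("conditiononset", "conditionlongDuration")))
  onset <- fit[fit$term == "conditiononset", ]
  expect_gt(onset$beta, 0.5)
})

test_that("untestable pairs return NA rows; collinearity is reported", {
  d <- two_group_scores()
  d$u[1:17] <- NA
  fit <- fit_score_model(d, "condition", model = "linear")
  expect_true(is.na(fit$p_raw))
  expect_equal(fit$n_dropped, 17)

  d2 <- two_group_scores()
  d2$dup <- as.numeric(d2$condition == "g2")
  expect_error(fit_score_model(d2, "condition", covariates = "dup",
                               model = "linear"), "collinear")
})

test_that("linear model overstates evidence driven by a minority of subjects", {
  # effect present in only 2 of 8 case subjects: the linear model ignores
  # the subject correlation and gives a smaller p than the mixed model
  set.seed(77)
  m <- 16; k <- 4
  subj <- rep(sprintf("s%02d", 1:m), each = k)
  cond <- rep(rep(c("ctrl", "case"), each = m / 2), each = k)
  u <- rnorm(m * k, 0, 0.5)
  driver <- subj %in% c("s09", "s10") # 2 of the 8 case subjects
  u[driver] <- u[driver] + 3
  d <- tibble::tibble(u = u, condition = cond, subject = subj)
  p_lin <- fit_score_model(d, "condition", model = "linear")$p_raw
  p_mix <- fit_score_model(d, "condition", subject = "subject",
                           model = "mixed")$p_raw
  expect_lt(p_lin, p_mix)
})

test_that("BH adjustment follows the step-up procedure across pairs", {
  base <- tibble::tibble(
    type_i = c("A", "A", "B", "B"), type_j = c("A", "B", "A", "B"),
    term = "conditiong2", beta = c(1, -1, 2, 0.5), se = 1, df = 10, t = 1,
    p_raw = c(0.01, 0.02, 0.03, 0.04), n_used = 10, n_dropped = 0,
    model = "linear", boundary = NA, subject_var = NA_real_,
    residual_var = 1, direction = c(1, -1, 1, 1)
  )
  res <- structure(list(results = base, config = list()),
                   class = "coloc_results")
  bh <- adjust_pvalues(res, "BH")
  expect_equal(bh$results$p_adjusted, rep(0.04, 4))
  expect_true(all(bh$results$p_adjusted >= bh$results$p_raw))
  none <- adjust_pvalues(res, "none")
  expect_equal(none$results$p_adjusted, none$results$p_raw)
  single <- res
  single$results <- base[2, ]
  expect_equal(adjust_pvalues(single, "BH")$results$p_adjusted, 0.02)
})

test_that("the signed significance matrix encodes direction and magnitude", {
  base <- tibble::tibble(
    type_i = c("A", "A", "B", "B"), type_j = c("A", "B", "A", "B"),
    term = "conditiong2", beta = c(1, -1, 0.5, NA), se = 1, df = 10, t = 1,
    p_raw = c(0.01, 0.001, 1, NA), n_used = 10, n_dropped = 0,
    model = "linear", boundary = NA, subject_var = NA_real_,
    residual_var = 1, direction = c(1, -1, 1, NA)
  )
  res <- structure(
    list(results = dplyr::mutate(base, p_adjusted = p_raw),
         config = list()),
    class = "coloc_results"
  )
  m <- signed_logp_matrix(res)
  expect_equal(m["A", "A"], 2)       # p = 0.01, beta > 0
  expect_equal(m["A", "B"], -3)      # p = 0.001, beta < 0
  expect_equal(m["B", "A"], 0)       # p = 1
  expect_true(is.na(m["B", "B"]))    # untestable pair stays missing
  plt <- autoplot(res)
  expect_s3_class(plt, "ggplot")
})

test_that("the full pipeline runs end to end on a simulated study", {
  sim <- simulate_study(sim_config(n_subjects = 8,
                                   cell_counts = c(100, 200)),
                        regime = "difference", seed = 5)
  res <- test_coloc(sim, condition = "condition", subject = "subject_id")
  tbl <- tidy(res)
  expect_equal(nrow(tbl), 4)
  expect_true(all(tbl$model == "mixed"))
  expect_true(all(tbl$p_raw >= 0 & tbl$p_raw <= 1, na.rm = TRUE))
  expect_equal(tbl$direction, sign(tbl$beta))
  expect_equal(glance(res)$n_pairs, 4)

  # reusing precomputed scores gives identical results
  s <- score_pairs(sim)
  res2 <- test_coloc(sim, condition = "condition", subject = "subject_id",
                     scores = s)
  expect_equal(tidy(res2)$p_raw, tbl$p_raw)

  # forcing the linear model changes the df but still tests all pairs
  res_lin <- test_coloc(sim, condition = "condition", model = "linear",
                        scores = s)
  expect_true(all(tidy(res_lin)$model == "linear"))

  out <- withr::local_tempdir()
  export_results(res, out)
  expect_true(file.exists(file.path(out, "results.csv")))
  expect_true(file.exists(file.path(out, "signed_logp_matrix.csv")))
  expect_true(file.exists(file.path(out, "heatmap.png")))
})

test_that("permuting condition labels across subjects yields uniform p-values", {
  # homogeneous counts keep the score model well specified, so the
  # permutation null should produce uniform p-values
  sim <- simulate_study(sim_config(n_subjects = 16, cell_counts = 200),
                        regime = "null", seed = 9)
  scores <- score_pairs(sim)
  vm <- fit_variance_surface(scores)
  sc <- compute_weights(scores, vm)
  meta <- sim$images[, c("image_id", "subject_id", "condition")]
  sub <- dplyr::left_join(sc[sc$type_i == "A" & sc$type_j == "B", ],
                          meta, by = "image_id")
  subj_tbl <- unique(meta[, c("subject_id", "condition")])
  set.seed(13)
  p_perm <- replicate(200, {
    relabel <- setNames(sample(subj_tbl$condition), subj_tbl$subject_id)
    d <- sub
    d$condition <- relabel[d$subject_id]
    suppressWarnings(
      fit_score_model(d, "condition", subject = "subject_id",
                      model = "mixed")$p_raw
    )
  })
  ks <- suppressWarnings(ks.test(p_perm, "punif"))
  expect_gt(ks$p.value, 0.01)
})
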