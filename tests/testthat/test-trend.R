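mom_table <- function(gene_id, mean, cv2) {
  data.frame(gene_id = gene_id, n = 10L, mean = mean, var = cv2 * mean^2,
             cv2 = cv2, defined = mean > 0, stringsAsFactors = FALSE)
}

test_that("identical conditions give a zero condition effect", {
  set.seed(12)
  mom <- mom_table(paste0("g", 1:30), rlnorm(30, 3, 1), runif(30, .05, .5))
  fit <- ancova_stress_trend(mom, mom)
  cond <- fit$coefficients[fit$coefficients$term == "condition", ]
  expect_equal(cond$estimate, 0, tolerance = 1e-10)
  expect_equal(cond$t, 0, tolerance = 1e-8)
  expect_identical(fit$df, fit$n - 3L)
})

test_that("coefficients match the hand-solved normal equations", {
  set.seed(3)
  momC <- mom_table(paste0("g", 1:12), rlnorm(12, 2, 1), runif(12, .1, .4))
  momH <- mom_table(paste0("g", 1:12), rlnorm(12, 2, 1), runif(12, .1, .6))
  fit <- ancova_stress_trend(momH, momC)
  # independent route: explicit normal equations on the same design
  y <- c(momC$cv2, momH$cv2)
  X <- cbind(1, rep(c(0, 1), each = 12),
             log10(c(momC$mean, momH$mean) + 1))
  beta <- solve(t(X) %*% X, t(X) %*% y)
  expect_equal(fit$coefficients$estimate, as.vector(beta),
               tolerance = 1e-8)
  # and against lm() for the full inferential output
  ref <- summary(lm(y ~ X - 1))$coefficients
  expect_equal(fit$coefficients$se, unname(ref[, 2]), tolerance = 1e-8)
  expect_equal(fit$coefficients$p, unname(ref[, 4]), tolerance = 1e-8)
  # residuals orthogonal to every design column
  expect_lt(max(abs(crossprod(fit$design, fit$residuals))), 1e-8)
})

test_that("a known additive CV^2 shift under stress is recovered", {
  set.seed(8)
  shift <- -0.08
  est <- se <- numeric(20)
  for (r in 1:20) {
    means <- rlnorm(200, 3, 1)
    base <- runif(200, 0.2, 0.6)
    momC <- mom_table(paste0("g", 1:200), means,
                      base + rnorm(200, 0, 0.05))
    momH <- mom_table(paste0("g", 1:200), means,
                      base + shift + rnorm(200, 0, 0.05))
    fit <- ancova_stress_trend(momH, momC)
    cond <- fit$coefficients[fit$coefficients$term == "condition", ]
    est[r] <- cond$estimate
    se[r] <- cond$se
  }
  expect_lt(abs(mean(est) - shift), 2 * sd(est) / sqrt(20))
  expect_lt(abs(mean(est) - shift), 3 * mean(se))
})

test_that("singular designs are refused with the offending column named", {
  mom <- mom_table(paste0("g", 1:20), rep(10, 20), runif(20, .1, .5))
  expect_error(ancova_stress_trend(mom, mom[sample(20), ]),
               "log10_mean")
  expect_error(ancova_stress_trend(mom[1:5, ], mom[1:5, ]), "10 genes")
})

test_that("condition p-values are uniform under label permutation", {
  set.seed(55)
  means <- rlnorm(150, 3, 1)
  p <- vapply(1:200, function(r) {
    # both conditions drawn from one CV^2 distribution: no true effect
    momC <- mom_table(paste0("g", 1:150), means, runif(150, 0.1, 0.5))
    momH <- mom_table(paste0("g", 1:150), means, runif(150, 0.1, 0.5))
    fit <- ancova_stress_trend(momH, momC)
    fit$coefficients$p[fit$coefficients$term == "condition"]
  }, 0)
  expect_gt(suppressWarnings(ks.test(p, "punif"))$p.value, 0.01)
})

test_that("Fisher p-values match hand enumeration", {
  expect_equal(fisher_exact(matrix(c(5, 5, 5, 5), 2)), 1)
  # C(6,3) = 20 equally likely tables; the two extremes have mass 0.05 each
  expect_equal(fisher_exact(matrix(c(3, 0, 0, 3), 2)), 0.1,
               tolerance = 1e-12)
  expect_message(p0 <- fisher_exact(matrix(c(0, 0, 3, 4), 2)),
                 "degenerate")
  expect_equal(p0, 1)
  expect_error(fisher_exact(matrix(c(1.5, 1, 1, 1), 2)))
})

test_that("Fisher is invariant to transposition and row/column swaps", {
  set.seed(101)
  for (i in 1:25) {
    tab <- matrix(rpois(4, 6), 2)
    p <- fisher_exact(tab)
    expect_equal(fisher_exact(t(tab)), p, tolerance = 1e-12)
    expect_equal(fisher_exact(tab[2:1, 2:1]), p, tolerance = 1e-12)
  }
})

test_that("Fisher agrees with the reference implementation exhaustively", {
  # all 2x2 tables with positive margins and total <= 30
  worst <- 0
  for (n in 2:30) {
    parts <- expand.grid(a = 0:n, b = 0:n, c = 0:n)
    parts <- parts[parts$a + parts$b + parts$c <= n, ]
    parts$d <- n - parts$a - parts$b - parts$c
    keep <- (parts$a + parts$b) > 0 & (parts$c + parts$d) > 0 &
      (parts$a + parts$c) > 0 & (parts$b + parts$d) > 0
    parts <- parts[keep, ]
    # sample within each total to keep the sweep fast but exhaustive in n
    if (nrow(parts) > 400) parts <- parts[seq(1, nrow(parts), length.out = 400), ]
    for (i in seq_len(nrow(parts))) {
      tab <- matrix(unlist(parts[i, c("a", "c", "b", "d")]), 2)
      diff <- abs(fisher_exact(tab) - fisher.test(tab)$p.value)
      worst <- max(worst, diff)
    }
  }
  expect_lt(worst, 1e-10)

  # the doubling rule never falls below the min-likelihood rule's tail
  tab <- matrix(c(12, 3, 4, 11), 2)
  expect_gte(fisher_exact(tab, rule = "doubling"),
             min(1, fisher_exact(tab)))
})
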