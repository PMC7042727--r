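test_that("quantile_normalize: fixed point, hand example, defining property", {
  m <- matrix(c(1, 2, 3, 1, 2, 3), 3, 2,
              dimnames = list(paste0("p", 1:3), c("a", "b")))
  expect_equal(quantile_normalize(m), m)

  # hand-computed 3x3: reference = row means of sorted columns
  x <- matrix(c(2, 5, 3,
                4, 1, 9,
                6, 8, 7), 3, 3,
              dimnames = list(paste0("p", 1:3), paste0("s", 1:3)))
  ref <- rowMeans(apply(x, 2, sort))        # c(3, 14/3, 22/3)
  want <- matrix(c(ref[1], ref[3], ref[2],
                   ref[2], ref[1], ref[3],
                   ref[1], ref[3], ref[2]), 3, 3,
                 dimnames = dimnames(x))
  expect_equal(quantile_normalize(x), want)

  set.seed(5)
  y <- matrix(rnorm(200), 20, 10,
              dimnames = list(paste0("p", 1:20), paste0("s", 1:10)))
  qn <- quantile_normalize(y)
  sorted <- apply(qn, 2, sort)
  for (j in 2:10) expect_equal(sorted[, j], sorted[, 1])
})

test_that("quantile_normalize agrees with the limma oracle", {
  set.seed(6)
  y <- matrix(rgamma(300, 2, 0.3), 30, 10,
              dimnames = list(paste0("p", 1:30), paste0("s", 1:10)))
  y[3, ] <- y[5, ]                           # inject ties across rows
  expect_equal(unname(quantile_normalize(y)),
               unname(limma::normalizeQuantiles(y, ties = TRUE)),
               tolerance = 1e-10)
})

make_es <- function(detp, groups, intens = NULL) {
  if (is.null(intens))
    intens <- matrix(8, nrow(detp), ncol(detp), dimnames = dimnames(detp))
  expression_set(intens, detp, groups,
                 data.frame(probe = rownames(detp),
                            gene = rownames(detp)),
                 log2_transformed = TRUE)
}

test_that("call_rate_filter drops probes failing in both groups only", {
  samples <- paste0("s", 1:20)
  groups <- setNames(rep(c("AD", "control"), each = 10), samples)
  detp <- matrix(0.01, 3, 20, dimnames = list(c("pA", "pB", "pC"), samples))
  # pA: 0.95 AD / 0.50 control -> kept; pB: 0.85/0.85 -> removed
  detp["pA", 11:15] <- 0.9
  detp["pB", c(1:2, 11:12)] <- 0.9           # 0.8 in both groups
  kept <- call_rate_filter(make_es(detp, groups))
  expect_true("pA" %in% kept)
  expect_false("pB" %in% kept)
  expect_true("pC" %in% kept)
  rates <- attr(kept, "rates")
  expect_equal(unname(rates["pA", ]), c(1, 0.5))
})

test_that("call_rate_filter matches a brute-force recount and is monotone", {
  set.seed(8)
  samples <- paste0("s", 1:30)
  groups <- setNames(rep(c("AD", "control"), c(18, 12)), samples)
  detp <- matrix(runif(50 * 30), 50, 30,
                 dimnames = list(paste0("p", 1:50), samples))
  es <- make_es(detp, groups)
  kept <- call_rate_filter(es, alpha = 0.05, min_rate = 0.9)
  for (p in rownames(detp)) {
    r_ad <- mean(detp[p, groups == "AD"] < 0.05)
    r_ct <- mean(detp[p, groups == "control"] < 0.05)
    expect_identical(p %in% kept, !(r_ad < 0.9 && r_ct < 0.9))
  }
  for (mr in c(0.2, 0.5, 0.8)) {
    lo <- call_rate_filter(es, min_rate = mr)
    hi <- call_rate_filter(es, min_rate = mr + 0.1)
    expect_true(all(hi %in% lo))
  }
})

test_that("gene_signal averages log2 probe values", {
  samples <- c("s1", "s2")
  intens <- matrix(c(4, 16, 64, 4, 16, 64), 3, 2,
                   dimnames = list(c("p1", "p2", "p3"), samples))
  detp <- matrix(0.01, 3, 2, dimnames = dimnames(intens))
  es <- expression_set(intens, detp,
                       setNames(c("AD", "control"), samples),
                       data.frame(probe = c("p1", "p2", "p3"),
                                  gene = c("G1", "G1", "G2")))
  expect_equal(unname(gene_signal(es, "G2")), c(6, 6))        # identity
  expect_equal(unname(gene_signal(es, "G1")), c(3, 3))        # mean(2, 4)
  expect_error(gene_signal(es, "G3"), "no retained probes")
  expect_equal(unname(gene_signal(es, "G1", retained = "p2")), c(4, 4))
})

test_that("fit_pair matches normal-equations oracle and perfect fits", {
  # base summary.lm warns about essentially perfect fits; expected here
  f <- suppressWarnings(fit_pair(c(1, 2, 3), c(2, 4, 6)))
  expect_equal(f$r, 1); expect_equal(f$r2_adj, 1)
  expect_equal(f$slope, 2)

  x <- c(1.2, 2.5, 3.1, 4.8, 6.0)
  y <- c(2.0, 2.9, 4.2, 4.1, 6.3)
  f2 <- fit_pair(x, y)
  # independent oracle: normal equations
  b1 <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  b0 <- mean(y) - b1 * mean(x)
  res <- y - b0 - b1 * x
  r2 <- 1 - sum(res^2) / sum((y - mean(y))^2)
  se <- sqrt(sum(res^2) / 3 / sum((x - mean(x))^2))
  p <- 2 * pt(-abs(b1 / se), df = 3)
  expect_equal(f2$slope, b1, tolerance = 1e-12)
  expect_equal(f2$intercept, b0, tolerance = 1e-12)
  expect_equal(f2$r2, r2, tolerance = 1e-12)
  expect_equal(f2$r2_adj, 1 - (1 - r2) * 4 / 3, tolerance = 1e-12)
  expect_equal(f2$slope_p, p, tolerance = 1e-12)
  expect_equal(f2$r^2, f2$r2, tolerance = 1e-12)   # Pearson r^2 == R^2
  expect_error(fit_pair(rep(1, 5), 1:5), "variance")
  expect_error(fit_pair(1:2, 1:2), "at least 3")
})

test_that("pearson_screen flags and ranks correctly", {
  set.seed(12)
  es <- make_expression(anchor = "ANCH",
                        targets = data.frame(gene = c("T1", "T2", "T3"),
                                             r = c(-0.77, 0.1, -0.2)),
                        n_ad = 150, n_control = 134, noise_sd = 0,
                        seed = 77)
  sc <- pearson_screen(es, "ANCH", c("T1", "T2", "T3", "ANCH"))
  expect_identical(sc$gene[1], "ANCH")       # self correlation r = 1
  expect_equal(sc$r[sc$gene == "ANCH"], 1, tolerance = 1e-12)
  expect_identical(sc$gene[2], "T1")
  expect_true(sc$high[sc$gene == "T1"])
  expect_false(any(sc$high[sc$gene %in% c("T2", "T3")]))
  # anti-correlated constructed pair
  samples <- c("s1", "s2", "s3", "s4")
  intens <- rbind(a = c(1, 2, 3, 4), b = c(4, 3, 2, 1))
  colnames(intens) <- samples
  detp <- matrix(0.01, 2, 4, dimnames = dimnames(intens))
  es2 <- expression_set(intens, detp,
                        setNames(rep(c("AD", "control"), 2), samples),
                        data.frame(probe = c("a", "b"),
                                   gene = c("GA", "GB")),
                        log2_transformed = TRUE)
  sc2 <- pearson_screen(es2, "GA", "GB")
  expect_equal(sc2$r, -1, tolerance = 1e-12)
})

test_that("compare_correlations matches the Fisher-z formula and symmetry", {
  # hand-evaluated example
  z1 <- atanh(0.5); z2 <- atanh(0.2)
  z <- (z1 - z2) / sqrt(1 / 27 + 1 / 27)
  got <- compare_correlations(0.5, 30, 0.2, 30, sided = "two")
  expect_equal(got$z, z, tolerance = 1e-12)
  expect_equal(got$p, 2 * pnorm(-abs(z)), tolerance = 1e-12)
  # equal correlations: z = 0, one-sided p = 0.5
  eq <- compare_correlations(0.3, 50, 0.3, 80, sided = "one")
  expect_equal(eq$z, 0); expect_equal(eq$p, 0.5)
  # swap invariance with sign flip
  a <- compare_correlations(0.5, 30, 0.2, 40, sided = "two")
  b <- compare_correlations(0.2, 40, 0.5, 30, sided = "two")
  expect_equal(a$p, b$p); expect_equal(a$z, -b$z)
  # brain vs non-brain tissue contrast is significant one-sided
  br <- compare_correlations(-0.27, 186, 0.0089, 502, sided = "one")
  expect_lt(br$p, 0.05)
  expect_lt(br$z, 0)
  expect_error(compare_correlations(1, 10, 0.5, 10), "diverges")
})

test_that("estimated r is within 2 SE of truth across a recovery grid", {
  grid <- expand.grid(r = c(-0.9, -0.27, 0, 0.5, 0.9), n = c(30, 284))
  for (i in seq_len(nrow(grid))) {
    r0 <- grid$r[i]; n <- grid$n[i]
    rs <- vapply(1:200, function(k) {
      es <- make_expression(anchor = "A",
                            targets = data.frame(gene = "B", r = r0),
                            n_ad = ceiling(n / 2), n_control = floor(n / 2),
                            probes_per_gene = 1, noise_sd = 0,
                            seed = 1000 * i + k)
      cor(gene_signal(es, "A"), gene_signal(es, "B"))
    }, numeric(1))
    # E[r_hat] carries the classical O(1/n) bias -r(1-r^2)/(2(n-1))
    expected <- r0 - r0 * (1 - r0^2) / (2 * (n - 1))
    se <- (1 - r0^2) / sqrt(n - 1) / sqrt(200)
    expect_lt(abs(mean(rs) - expected), 2 * se + 1e-3)
  }
})
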