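test_that("VIP filtering is a strict threshold ordered by score", {
  v <- c(a = 1.2, b = 1.0, c = 0.9)
  expect_equal(vip_filter(v), "a")
  expect_equal(vip_filter(c(x = 0.3, y = 1.0)), character(0))
  expect_equal(vip_filter(c(lo = 1.1, hi = 2.0)), c("hi", "lo"))
  expect_error(vip_filter(c(1, NA)), "finite")
})

test_that("planted informative features pass the VIP screen reliably", {
  hits <- 0
  for (seed in 1:20) {
    set.seed(seed)
    n <- 40
    Z <- matrix(rnorm(n * 3), n, 3)
    X <- cbind(Z, matrix(rnorm(n * 17), n, 17))
    colnames(X) <- paste0("f", 1:20)
    y <- Z %*% c(2, -2, 1.5) + rnorm(n, sd = 0.3)
    sel <- vip_filter(vip(pls_fit(X, y, n_lv = 3)))
    if (all(c("f1", "f2", "f3") %in% sel)) hits <- hits + 1
  }
  expect_gte(hits, 19)   # >= 95% of seeded runs
})

test_that("shared markers are the panel intersection with provenance", {
  p <- shared_markers(list(m1 = c("A", "B", "C"), m2 = c("B", "C", "D")))
  expect_equal(p$selected, c("B", "C"))
  expect_named(p$provenance, c("m1", "m2"))

  same <- shared_markers(list(c("A", "B"), c("A", "B"), c("A", "B")))
  expect_equal(same$selected, c("A", "B"))

  expect_warning(shared_markers(list(c("A"), c("B"))), "no shared")
  expect_error(shared_markers(list(c("A"))), ">= 2")
  expect_error(shared_markers(list(c("A"), character(0))), "empty panel")
})

test_that("Duncan letters match a manual three-group walk-through", {
  # groups: A = {10, 12}, B = {9, 11}, C = {1, 3}; every within-group
  # variance is 2, so MSE = 2 with 3 error df and the critical ranges are
  # qtukey((1-a)^(k-1), k, 3) * sqrt(2/2) ~ 4.5 (span 2) and ~ 5.9 (span 3).
  # Ordered means 11, 10, 2: |11-10| = 1 (ns), |10-2| and |11-2| >> crit.
  res <- anova_duncan(list(A = c(10, 12), B = c(9, 11), C = c(1, 3)))
  expect_equal(res$MSE, 2)
  expect_equal(res$df_error, 3)
  tab <- res$table
  expect_equal(tab$group, c("A", "B", "C"))
  expect_equal(tab$letters, c("a", "a", "b"))

  # two groups 100 pooled SDs apart
  res2 <- anova_duncan(list(hi = c(100, 100.1, 99.9), lo = c(0, 0.1, -0.1)))
  expect_equal(res2$table$letters, c("a", "b"))
  expect_lt(res2$p_value, 1e-6)

  # five groups with equal means all share the leading letter
  g <- lapply(1:5, function(i) c(1, 2, 3))
  names(g) <- paste0("g", 1:5)
  res3 <- anova_duncan(g)
  expect_true(all(res3$table$letters == "a"))

  expect_error(anova_duncan(list(a = c(1, 1), b = c(2, 2))), "zero within")
  expect_error(anova_duncan(list(a = c(1, 2))), ">= 2 groups")
  expect_error(anova_duncan(list(a = c(1, 2), b = 3)), "n >= 2")
})

test_that("letter display is consistent with the pairwise range tests", {
  for (seed in 1:5) {
    set.seed(seed)
    vals <- lapply(1:5, function(i) rnorm(6, mean = sample(1:4, 1)))
    names(vals) <- paste0("g", 1:5)
    res <- tryCatch(anova_duncan(vals), error = function(e) NULL)
    if (is.null(res)) next
    tab <- res$table                     # ordered by decreasing mean
    k <- nrow(tab)
    ms <- tab$mean
    nh <- 6
    crit <- vapply(2:k, function(span)
      qtukey((1 - res$alpha)^(span - 1), span, res$df_error) *
        sqrt(res$MSE / nh), 0)
    share <- function(i, j) {
      any(strsplit(tab$letters[i], "")[[1]] %in%
            strsplit(tab$letters[j], "")[[1]])
    }
    for (i in 1:(k - 1)) for (j in (i + 1):k) {
      # protected nonsignificance: some covering interval within its range
      covered <- FALSE
      for (a in 1:i) for (b in j:k)
        if (ms[a] - ms[b] <= crit[b - a]) covered <- TRUE
      expect_equal(share(i, j), covered)
    }
  }
})

test_that("markers with fully distinct species letters separate at n = 19", {
  # the succinic-acid-like case: five species means far apart relative to
  # their SDs should earn five distinct letters in nearly every cohort
  tab <- bolete_marker_table()
  j <- which(tab$marker == "Succinic Acid")
  ok <- 0
  for (seed in 1:10) {
    ds <- generate_dataset(19, "NIR", seed = seed)
    res <- anova_duncan(split(ds$concentrations[, j], ds$labels))
    ok <- ok + (length(unique(res$table$letters)) == 5)
  }
  expect_gte(ok, 9)   # >= 90% of seeded runs
})

test_that("marker letter tables have the compendium shape", {
  ds <- generate_dataset(4, "NIR", seed = 2)
  lt <- marker_letter_table(ds$concentrations, ds$labels, units = ds$units)
  expect_equal(dim(lt), c(16, 5))
  expect_match(lt[1, 1], "^[0-9.]+ ± [0-9.]+\\^[a-e]+\\^$")
  expect_match(rownames(lt)[4], "g/kg")
})
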