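test_that("Anderson-Darling accepts normal and rejects uniform data", {
  expect_error(andersonDarlingNormality(rep(5, 20)), "degenerate")
  expect_error(andersonDarlingNormality(rnorm(5)), "n >= 8")

  # type-I simulation: large normal samples pass in >= 90% of repetitions
  set.seed(61)
  pNorm <- replicate(100, andersonDarlingNormality(rnorm(5000))$p.value)
  expect_gte(mean(pNorm > 0.05), 0.9)

  # power: a flat alternative at n = 5000 is rejected
  set.seed(62)
  expect_lt(andersonDarlingNormality(runif(5000))$p.value, 0.05)
})

test_that("Kruskal-Wallis matches the hand rank-sum formula", {
  # exchangeable identical groups: no evidence at all
  kw <- kruskalWallis(list(c(1, 2, 3), c(1, 2, 3), c(1, 2, 3)))
  expect_equal(kw$statistic, 0)
  expect_equal(kw$p.value, 1)
  expect_equal(kw$df, 2L)

  # all observations identical: defined as H = 0, p = 1
  kw0 <- kruskalWallis(list(c(4, 4), c(4, 4, 4)))
  expect_equal(kw0$statistic, 0)
  expect_equal(kw0$p.value, 1)

  # three separated tie-free groups: H = 7.2 by the rank-sum formula
  g3 <- list(c(1, 2, 3), c(4, 5, 6), c(7, 8, 9))
  kw3 <- kruskalWallis(g3)
  expect_equal(kw3$statistic, 7.2)
  expect_equal(kw3$statistic, oracleKruskalH(g3))
  expect_equal(kw3$df, 2L)
  expect_equal(kw3$p.value, stats::pchisq(7.2, 2, lower.tail = FALSE))

  # two groups: rank sums R1 = 6, R2 = 15 give H = 27/7
  kw2 <- kruskalWallis(list(c(1, 2, 3), c(4, 5, 6)))
  expect_equal(kw2$statistic, 27 / 7)

  # seeded data with ties: match the independent oracle to 1e-8
  set.seed(31)
  for (i in 1:10) {
    g <- list(round(rnorm(12, 0, 2)), round(rnorm(15, 0.5, 2)),
              round(rnorm(9, 1, 2)))
    expect_equal(kruskalWallis(g)$statistic, oracleKruskalH(g),
                 tolerance = 1e-8)
  }
  expect_error(kruskalWallis(list(c(1, 2))), "at least 2 groups")
})

test_that("rank-sum test matches enumeration and normal-approximation oracles", {
  # perfect overlap: p = 1
  expect_equal(wilcoxonRankSum(c(1, 2, 3), c(1, 2, 3))$p.value, 1)

  # maximal separation, exact path: p = 2/20 = 0.1
  w <- wilcoxonRankSum(c(1, 2, 3), c(10, 11, 12))
  expect_true(w$exact)
  expect_equal(w$p.value, 0.1)
  expect_equal(w$p.value, oracleExactRankSumP(c(1, 2, 3), c(10, 11, 12)))

  # exact p equals full enumeration for random tie-free samples, n <= 8
  set.seed(77)
  for (i in 1:8) {
    na <- sample(3:8, 1); nb <- sample(3:8, 1)
    pool <- sample(1000, na + nb)  # distinct -> tie-free
    a <- pool[seq_len(na)]; b <- pool[-seq_len(na)]
    got <- wilcoxonRankSum(a, b)
    expect_true(got$exact)
    expect_equal(got$p.value, oracleExactRankSumP(a, b), tolerance = 1e-12)
  }

  # large/tied samples: normal approximation with tie + continuity correction
  set.seed(78)
  for (i in 1:8) {
    a <- round(rnorm(40, 0, 3)); b <- round(rnorm(35, 0.8, 3))
    got <- wilcoxonRankSum(a, b)
    expect_false(got$exact)
    expect_equal(got$p.value, oracleNormalRankSumP(a, b), tolerance = 1e-6)
  }
})

test_that("two-group Kruskal-Wallis agrees with the rank-sum approximation", {
  set.seed(41)
  for (i in 1:10) {
    a <- rnorm(30); b <- rnorm(30, 0.4)
    pkw <- kruskalWallis(list(a, b))$p.value
    pw <- oracleNormalRankSumP(a, b)
    expect_lt(abs(pkw - pw), 0.01)
  }
})

test_that("compareOperators assembles the per-variable report", {
  # synthetic results table: 3 physicians, 48 images each, one shifted GSM
  set.seed(55)
  mkTable <- function(shift3 = 0) {
    n <- 48
    rows <- lapply(c("phy1", "phy2", "phy3"), function(d) {
      sh <- if (d == "phy3") shift3 else 0
      pct <- matrix(abs(rnorm(n * 14, 100 / 14, 2)), n, 14)
      pct <- 100 * pct / rowSums(pct)
      df <- data.frame(category = "random", physician_id = d,
                       device_id = "dev1", gsm = rnorm(n, 90, 6) + sh)
      cbind(df, stats::setNames(as.data.frame(pct), sprintf("pct_%02d", 1:14)))
    })
    do.call(rbind, rows)
  }

  # null table: everything from one distribution, flags near alpha
  nullRep <- compareOperators(mkTable(0), "random")
  expect_s4_class(nullRep, "StatReport")
  expect_equal(nrow(nullRep@omnibus), 15L)
  expect_equal(nrow(nullRep@pairwise), 45L)  # 3 pairs x 15 variables
  expect_equal(nullRep@nTests, 60L)
  fracSig <- mean(nullRep@pairwise$significant)
  expect_lt(fracSig, 0.2)

  # power: a +30 GSM shift for phy3 is flagged for both pairs involving it
  shiftRep <- compareOperators(mkTable(30), "random")
  gsmRows <- shiftRep@pairwise[shiftRep@pairwise$variable == "gsm", ]
  hit <- gsmRows$significant[gsmRows$group_a == "phy3" | gsmRows$group_b == "phy3"]
  expect_true(all(hit))
  expect_equal(length(hit), 2L)
  counts <- significantCounts(shiftRep)
  expect_true(all(counts$gsm_significant[counts$group_a == "phy3" |
                                           counts$group_b == "phy3"]))

  # a category with a single group is an error
  one <- mkTable(0); one <- one[one$physician_id == "phy1", ]
  expect_error(compareOperators(one, "random"), "insufficient groups")
})

test_that("stat report serializes to a tidy CSV", {
  set.seed(9)
  tbl <- data.frame(category = "standardized",
                    physician_id = rep(c("a", "b"), each = 20),
                    device_id = "dev1", gsm = rnorm(40, 90, 5))
  for (k in sprintf("pct_%02d", 1:14)) tbl[[k]] <- runif(40, 0, 15)
  rep <- compareOperators(tbl, "standardized")
  tf <- tempfile(fileext = ".csv")
  on.exit(unlink(tf))
  writeStatReport(rep, tf)
  back <- utils::read.csv(tf)
  expect_equal(nrow(back), 15L)
  expect_setequal(names(back),
                  c("variable", "group_a", "group_b", "statistic", "p", "significant"))
  expect_equal(back$significant, back$p < 0.05)
})
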