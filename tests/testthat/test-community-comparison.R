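outdoor_md <- function(ids, location = "Brooklyn", season = "winter") {
  data.frame(sample_id = ids, home_id = "", room = "other",
             sample_type = "outdoor_dust_fall", location = location,
             season = season, is_control = FALSE, stringsAsFactors = FALSE)
}

test_that("outdoor pooling means relative abundances then renormalizes", {
  m <- matrix(c(10, 30,
                90, 70), 2, 2, byrow = TRUE,
              dimnames = list(c("a", "b"), c("o1", "o2")))
  x <- count_matrix(m)
  md <- outdoor_md(c("o1", "o2"))
  prof <- pool_outdoor(x, md, "Brooklyn", "winter")
  expect_equal(unname(prof$profile), c(0.2, 0.8))  # mean(0.1,0.3), mean(0.9,0.7)
  expect_equal(prof$n_source_samples, 2)
  expect_equal(sum(prof$profile), 1, tolerance = 1e-9)
  # single sample pools to its own relative profile
  one <- pool_outdoor(count_matrix(m[, 1, drop = FALSE]), md[1, ],
                      "Brooklyn", "winter")
  expect_equal(unname(one$profile), c(0.1, 0.9))
  # order invariance
  rev2 <- pool_outdoor(count_matrix(m[, 2:1]), md[2:1, ],
                       "Brooklyn", "winter")
  expect_equal(rev2$profile, prof$profile)
  expect_error(pool_outdoor(x, md, "Manhattan", "summer"),
               "available pairings")
})

test_that("Bray-Curtis matches its formula, bounds and symmetry", {
  expect_equal(bray_curtis(c(6, 2), c(2, 2)), 1 / 3)
  expect_equal(bray_curtis(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(bray_curtis(c(1, 0), c(0, 5)), 1)
  expect_error(bray_curtis(c(0, 0), c(0, 0)), "undefined")
  set.seed(31)
  for (i in 1:50) {
    p <- runif(20); q <- runif(20)
    d <- bray_curtis(p, q)
    expect_equal(d, bray_curtis(q, p))
    expect_true(d >= 0 && d <= 1)
    # vegan as independent oracle
    expect_equal(d, as.numeric(vegan::vegdist(rbind(p, q), "bray")),
                 tolerance = 1e-12)
  }
})

test_that("distances on relative abundances ignore depth rescaling", {
  set.seed(32)
  p <- runif(15); q <- runif(15)
  rp <- p / sum(p); rq <- q / sum(q)
  expect_equal(bray_curtis(rp, rq),
               bray_curtis((7 * p) / sum(7 * p), rq), tolerance = 1e-12)
})

test_that("indoor samples pair with their own location-season composite", {
  taxa <- paste0("t", 1:4)
  out <- matrix(c(10, 20, 30, 40,
                  5, 5, 5, 5), 4, 2,
                dimnames = list(taxa, c("o1", "o2")))
  ind <- matrix(c(1, 2, 3, 4,      # proportional to composite o1-only? no: both pooled
                  0, 0, 0, 8), 4, 2,
                dimnames = list(taxa, c("i1", "i2")))
  m <- cbind(out, ind)
  md <- rbind(outdoor_md(c("o1", "o2")),
              data.frame(sample_id = c("i1", "i2"), home_id = c("H1", "H2"),
                         room = "living_room", sample_type = "dust_fall",
                         location = "Brooklyn", season = "winter",
                         is_control = FALSE, stringsAsFactors = FALSE))
  x <- count_matrix(m)
  comp <- pool_outdoor(x, md, "Brooklyn", "winter")
  rec <- match_and_measure(x, md, list(comp))
  expect_equal(nrow(rec), 2)   # outdoor samples are never paired as indoor
  expect_setequal(rec$sample_id, c("i1", "i2"))
  expect_equal(rec$shared_taxa[rec$sample_id == "i1"], 4)
  expect_equal(rec$shared_taxa[rec$sample_id == "i2"], 1)
  # an indoor sample identical to the composite has distance 0
  prof <- comp$profile
  m2 <- cbind(out, i3 = round(prof * 1e6))
  md2 <- rbind(outdoor_md(c("o1", "o2")),
               data.frame(sample_id = "i3", home_id = "H3", room = "bedroom",
                          sample_type = "vacuum", location = "Brooklyn",
                          season = "winter", is_control = FALSE,
                          stringsAsFactors = FALSE))
  rec2 <- match_and_measure(count_matrix(m2), md2, list(comp))
  expect_equal(rec2$bray_curtis, 0, tolerance = 1e-5)
  # a missing pairing is an error naming it
  md3 <- md2; md3$season[3] <- "summer"
  expect_error(match_and_measure(count_matrix(m2), md3, list(comp)),
               "Brooklyn-summer")
})

test_that("disjoint indoor communities sit at distance 1 with 0 shared", {
  m <- matrix(c(10, 0,
                20, 0,
                0, 7), 3, 2, byrow = TRUE,
              dimnames = list(paste0("t", 1:3), c("o1", "i1")))
  md <- rbind(outdoor_md("o1"),
              data.frame(sample_id = "i1", home_id = "H1", room = "bedroom",
                         sample_type = "vacuum", location = "Brooklyn",
                         season = "winter", is_control = FALSE,
                         stringsAsFactors = FALSE))
  x <- count_matrix(m)
  rec <- match_and_measure(x, md, list(pool_outdoor(x, md, "Brooklyn",
                                                    "winter")))
  expect_equal(rec$bray_curtis, 1)
  expect_equal(rec$shared_taxa, 0)
})

test_that("rank comparisons choose the right test and detect shifts", {
  set.seed(33)
  d <- runif(30, 0.3, 0.6)
  same <- compare_distance_distributions(c(d, d),
                                         rep(c("no", "yes"), each = 30))
  expect_equal(same$test, "wilcoxon_mann_whitney")
  expect_gt(same$p_value, 0.99)
  # damaged-home distances shifted upward are detected
  hits <- replicate(20, {
    a <- runif(30, 0.3, 0.6); b <- runif(30, 0.3, 0.6) + 0.2
    compare_distance_distributions(c(a, b),
                                   rep(c("no", "yes"), each = 30))$p_value < 0.01
  })
  expect_gte(sum(hits), 19)
  three <- compare_distance_distributions(runif(60),
                                          rep(c("0", "low", "high"), 20))
  expect_equal(three$test, "kruskal_wallis")
  # undersized groups are dropped with a warning, the rest still compared
  expect_warning(
    res <- compare_distance_distributions(
      runif(61), c(rep("a", 30), rep("b", 30), "c")),
    "fewer than 2")
  expect_equal(res$test, "wilcoxon_mann_whitney")
})

test_that("rare-taxon filtering never increases shared-taxa counts", {
  set.seed(34)
  m <- matrix(rnbinom(200, mu = 5, size = 0.3), 20, 10,
              dimnames = list(paste0("t", 1:20), paste0("s", 1:10)))
  m[, 1] <- m[, 1] + 1  # outdoor sample has everything
  md <- rbind(outdoor_md("s1"),
              data.frame(sample_id = paste0("s", 2:10),
                         home_id = paste0("H", 2:10), room = "bedroom",
                         sample_type = "vacuum", location = "Brooklyn",
                         season = "winter", is_control = FALSE,
                         stringsAsFactors = FALSE))
  x <- count_matrix(m)
  full <- match_and_measure(x, md, list(pool_outdoor(x, md, "Brooklyn",
                                                     "winter")))
  xf <- filter_rare(x, 0.01)
  filt <- match_and_measure(xf, md,
                            list(pool_outdoor(xf, md, "Brooklyn", "winter")))
  expect_true(all(filt$shared_taxa <= full$shared_taxa))
})
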