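test_that("count TSV round trip is exact and bad cells are located", {
  x <- toy_counts()
  p <- tempfile(fileext = ".tsv")
  write_counts(x, p)
  y <- read_counts(p)
  expect_identical(y$counts, x$counts)
  expect_identical(y$orig_totals, x$orig_totals)
  # large integers survive (exact below 2^53)
  big <- count_matrix(matrix(c(2^40, 1, 3, 2^41 + 7), 2, 2,
                             dimnames = list(c("a", "b"), c("s1", "s2"))))
  write_counts(big, p)
  expect_identical(read_counts(p)$counts, big$counts)
  writeLines(c("asv_id\tS1\tS2", "ASV_1\t5\t-1", "ASV_2\t0\t2"), p)
  expect_error(read_counts(p), "ASV_1.*S2")
})

test_that("contaminant score follows the documented prevalence formula", {
  # 3 controls, 20 true samples
  m <- matrix(0L, 3, 23,
              dimnames = list(c("contam", "clean", "ubiquitous"),
                              c(paste0("C", 1:3), paste0("T", 1:20))))
  m["contam", 1:3] <- 5L; m["contam", 4] <- 2L      # 3/3 ctrl, 1/20 true
  m["clean", 4:23] <- 7L                            # 0/3 ctrl
  m["ubiquitous", ] <- 9L                           # everywhere
  md <- data.frame(sample_id = colnames(m),
                   is_control = c(TRUE, TRUE, TRUE, rep(FALSE, 20)))
  x <- count_matrix(m)
  fl <- flag_contaminants(x, md)
  sc <- attr(fl, "score")
  p <- function(k, n) (k + 0.5) / (n + 1)           # independent evaluation
  expect_equal(unname(sc["contam"]),
               p(3, 3) / (p(3, 3) + p(1, 20)))
  expect_equal(unname(sc["ubiquitous"]),
               p(3, 3) / (p(3, 3) + p(20, 20)))
  expect_true("contam" %in% fl)
  expect_false("clean" %in% fl)         # absent from controls
  expect_false("ubiquitous" %in% fl)    # equal full prevalence scores < 0.5
  # threshold 1.0 flags nothing here (no ASV attains the maximal score)
  expect_length(flag_contaminants(x, md, threshold = 1), 0)
  expect_error(flag_contaminants(x, md[0, ]), "control")
})

test_that("species subsets keep all matching ASVs and original offsets", {
  x <- toy_counts(); tx <- toy_taxonomy()
  sub <- subset_by_species(x, tx, "Aspergillus versicolor")
  expect_setequal(rownames(sub$counts), c("ASV_1", "ASV_3"))  # both ASVs
  expect_identical(sub$orig_totals, x$orig_totals)            # full totals
  expect_equal(unname(colSums(sub$counts)), c(5, 2, 14))
  expect_warning(sub0 <- subset_by_species(x, tx, "Agaricus bisporus"),
                 "no ASVs")
  expect_equal(nrow(sub0$counts), 0)
  # empty species never matches, even if asked for literally
  expect_warning(subset_by_species(x, tx, ""), "no ASVs")
})

test_that("group aggregation sums members and conserves totals", {
  x <- toy_counts()
  map <- c(ASV_1 = "g1", ASV_2 = "g1", ASV_3 = "g2")
  g <- aggregate_group(x, map, groups = c("g1", "g2", "gempty"))
  expect_equal(g["g1", ], c(S1 = 12, S2 = 3, S3 = 10))
  expect_equal(unname(g["gempty", ]), c(0, 0, 0))
  # conservation: groups + unmapped = sample totals
  unmapped <- setdiff(rownames(x$counts), names(map))
  expect_equal(colSums(g) + colSums(x$counts[unmapped, , drop = FALSE]),
               colSums(x$counts))
})

test_that("relative and absolute abundance follow their definitions", {
  expect_equal(relative_abundance(250, 10000), 0.025)
  expect_equal(absolute_abundance(0.025, 1e6), 2.5e4)
  expect_equal(absolute_abundance(0.025, 1e6, sample_type = "vacuum"), 2.5e4)
  expect_error(absolute_abundance(0.025, 1e6, sample_type = "swab"),
               "vacuum and dust fall")
  expect_error(relative_abundance(1, 0), "positive")
})

test_that("home swab compositing averages proportions", {
  m <- matrix(c(20, 40,
                80, 60), 2, 2, byrow = TRUE,
              dimnames = list(c("a", "b"), c("sw1", "sw2")))
  md <- data.frame(sample_id = c("sw1", "sw2"), home_id = c("H1", "H1"))
  comp <- average_home_swabs(count_matrix(m), md)
  expect_equal(unname(comp$counts[, "H1"]), c(30, 70))  # mean(0.2,0.4)*100
  # identical swabs compose to themselves
  m2 <- cbind(m[, 1], m[, 1]); dimnames(m2) <- dimnames(m)
  comp2 <- average_home_swabs(count_matrix(m2), md)
  expect_equal(unname(comp2$counts[, "H1"]), unname(m[, 1]))
  # single-swab homes are excluded with a message
  md3 <- data.frame(sample_id = c("sw1", "sw2"), home_id = c("H1", "H2"))
  expect_message(expect_error(average_home_swabs(count_matrix(m), md3),
                              "two or more"), "H1")
})

test_that("rare-taxon filter drops taxa never exceeding the floor", {
  m <- matrix(c(5,    5,      # 0.05% everywhere (depth 10000)
                20,   5,      # 0.2% in sample 1
                9975, 9990),
              3, 2, byrow = TRUE,
              dimnames = list(c("rare", "sometimes", "common"),
                              c("s1", "s2")))
  x <- count_matrix(m)
  f <- filter_rare(x, 0.001)
  expect_setequal(rownames(f$counts), c("sometimes", "common"))
  expect_identical(filter_rare(x, 0)$counts, x$counts)  # identity at 0
  expect_identical(f$orig_totals, x$orig_totals)
})

test_that("BIOM JSON tables read to the same matrix as TSV", {
  skip_if_not_installed("biomformat")
  x <- toy_counts()
  bp <- tempfile(fileext = ".biom")
  biomformat::write_biom(biomformat::make_biom(x$counts), bp)
  y <- read_counts(bp)
  expect_equal(y$counts[rownames(x$counts), colnames(x$counts)], x$counts)
})
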