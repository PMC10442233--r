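write_table_tsv <- function(df) {
  f <- tempfile(fileext = ".tsv")
  utils::write.table(df, f, sep = "\t", quote = FALSE, row.names = FALSE)
  f
}

test_that("domain tables read, validate and canonicalize on ingest", {
  df <- data.frame(
    domain_id = c("d1", "d2", "d3"), homology_id = "H1",
    family_id = "H1.F1",
    topology = c("1234:udud", "4321:dudu", ""))
  tab <- read_domain_table(write_table_tsv(df))
  expect_s3_class(tab, "observation_table")
  expect_equal(nrow(tab), 3)
  # 4321:dudu is a symmetry image of 1234:udud: same canonical key
  expect_identical(tab$topology[1], tab$topology[2])

  bad <- df
  bad$topology[2] <- "1342:zz"
  expect_error(read_domain_table(write_table_tsv(bad)), "row 2")
  dup <- df
  dup$domain_id[2] <- "d1"
  dup$topology[2] <- "1234:udud"
  expect_error(read_domain_table(write_table_tsv(dup)), "duplicate")
  expect_error(read_domain_table(write_table_tsv(df[, 1:3])), "missing columns")
  split_fam <- df
  split_fam$homology_id <- c("H1", "H2", "H1")
  expect_error(read_domain_table(write_table_tsv(split_fam)),
               "more than one homology")
})

test_that("occupation ratios follow the family-mean definition", {
  one_family <- make_domain_table_fixture(data.frame(
    topology = "1234:udud", homologies = 1, families = 1, fraction = 1))
  expect_equal(occupation_ratio(one_family, "1234:udud"), 1.0)
  two_families <- make_domain_table_fixture(data.frame(
    topology = "1234:udud", homologies = 1, families = 2, fraction = "1,1/2"))
  expect_equal(occupation_ratio(two_families, "1234:udud"), 0.75)
  expect_equal(occupation_ratio(two_families, "1324:uuuu"), 0)
  expect_error(occupation_ratio(two_families[0, ], "1234:udud"), "empty")
})

test_that("observation frequency sums occupation ratios across homologies", {
  tab <- make_domain_table_fixture(data.frame(
    topology = c("1234:udud", "1234:udud"),
    homologies = c(1, 1), families = c(1, 2),
    fraction = c("1", "1,1/2")))
  expect_equal(observation_frequency(tab, "1234:udud"), 1.75)
  # symmetry images of the query hit the same key
  expect_equal(observation_frequency(tab, "4321:dudu"), 1.75)
  expect_equal(observation_frequency(tab, "2134:uuud"), 0)
  expect_equal(observation_frequency(NULL, "1234:udud"), 0)
})

test_that("the unobserved label uses a strict quarter threshold", {
  expect_identical(label_observed(0), "unobserved")
  expect_identical(label_observed(0.2), "unobserved")
  expect_identical(label_observed(0.25), "observed")   # strict less-than
  expect_identical(label_observed(1.75), "observed")
  expect_identical(label_observed(c(0.1, 0.3)), c("unobserved", "observed"))
  expect_identical(label_observed(0.3, threshold = 1 / 2), "unobserved")
  expect_error(label_observed(1, threshold = -1), "non-negative")
})

test_that("frequency grows monotonically as matching records accumulate", {
  freqs <- vapply(1:4, function(h) {
    tab <- make_domain_table_fixture(data.frame(
      topology = "1234:udud", homologies = h, families = 2,
      fraction = "1,1/2"))
    observation_frequency(tab, "1234:udud")
  }, numeric(1))
  expect_true(all(diff(freqs) > 0))
  expect_equal(freqs, 0.75 * (1:4))
})

test_that("novel-fold prediction returns free, unobserved topologies", {
  # no observations: every frustration-free four-strand topology is novel
  novel_all <- predict_novel_folds(4)
  expect_equal(nrow(novel_all), 43)
  expect_true(all(novel_all$frustration_free))
  expect_true(all(novel_all$status == "unobserved"))

  # a heavily observed meander drops out
  tab <- make_domain_table_fixture(data.frame(
    topology = "1234:udud", homologies = 10, families = 1, fraction = 1))
  novel <- predict_novel_folds(4, tab)
  expect_equal(nrow(novel), 42)
  expect_false("1234:udud" %in% novel$topology)

  # marking 35 of the 43 free topologies observed leaves 8 novel folds
  cls <- classify_all(4, detail = FALSE)
  free <- cls$topology[cls$frustration_free]
  tab35 <- make_domain_table_fixture(data.frame(
    topology = free[1:35], homologies = 1, families = 1, fraction = 1))
  novel8 <- predict_novel_folds(4, tab35)
  expect_equal(nrow(novel8), 8)
  expect_setequal(novel8$topology, free[36:43])
  # prediction is a subset of the free set, disjoint from the observed set
  expect_true(all(novel8$topology %in% free))
  expect_length(intersect(novel8$topology, free[1:35]), 0)
})

test_that("whole-space scoring table is complete and TSV-exportable", {
  tab <- make_domain_table_fixture(data.frame(
    topology = "1234:udud", homologies = 1, families = 1, fraction = 1))
  sc <- score_observed(4, tab)
  expect_equal(nrow(sc), 96)
  expect_equal(sum(sc$frequency), 1)
  expect_equal(sum(sc$frustration_free), 43)
  f <- tempfile(fileext = ".tsv")
  write_frequency_tsv(sc, f)
  expect_equal(nrow(read.delim(f)), 96)
})

test_that("fixture construction realizes requested fractions exactly", {
  tab <- make_domain_table_fixture(data.frame(
    topology = "1234:udud", homologies = 2, families = 3,
    fraction = "1,1/2,1/4"))
  expect_equal(observation_frequency(tab, "1234:udud"), 2 * (1 + 0.5 + 0.25) / 3)
  empty <- make_domain_table_fixture(data.frame())
  expect_equal(nrow(empty), 0)
  expect_equal(observation_frequency(empty, "1234:udud"), 0)
  expect_error(make_domain_table_fixture(data.frame(
    topology = "1234:udud", homologies = 1, families = 1, fraction = 1.5)),
    "\\[0,1\\]")
  # deterministic under a fixed seed
  t1 <- make_domain_table_fixture(data.frame(
    topology = "1234:udud", homologies = 1, families = 2, fraction = "1,1/2"),
    seed = 7)
  t2 <- make_domain_table_fixture(data.frame(
    topology = "1234:udud", homologies = 1, families = 2, fraction = "1,1/2"),
    seed = 7)
  expect_identical(t1, t2)
})
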