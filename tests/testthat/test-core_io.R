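test_that("wide and long layouts read to the same matrix and round-trip", {
  mat <- tiny_matrix()
  fw <- withr::local_tempfile(fileext = ".csv")
  fl <- withr::local_tempfile(fileext = ".csv")
  write_metabolome(mat, fw, layout = "wide")
  write_metabolome(mat, fl, layout = "long")
  mw <- read_metabolome(fw, layout = "wide")
  ml <- read_metabolome(fl, layout = "long")
  expect_equal(mw$values, mat$values, tolerance = 1e-12)
  expect_equal(ml$values, mw$values, tolerance = 1e-12)
  cols <- c("sample_id", "variety", "timepoint_hai", "replicate")
  expect_equal(as.data.frame(mw$samples)[cols],
               as.data.frame(mat$samples)[cols])
})

test_that("a fuzzed corpus of well-formed tables reads cleanly", {
  for (seed in 1:10) {
    mat <- tiny_matrix(n_met = sample(2:8, 1), reps = sample(2:3, 1),
                       seed = seed)
    f <- withr::local_tempfile(fileext = ".csv")
    layout <- sample(c("wide", "long"), 1)
    write_metabolome(mat, f, layout = layout)
    rt <- read_metabolome(f, layout = layout)
    expect_equal(rt$values, mat$values, tolerance = 1e-12)
  }
})

test_that("missing cells survive a long-layout round trip", {
  mat <- tiny_matrix()
  mat$values[2, 3] <- NA
  f <- withr::local_tempfile(fileext = ".csv")
  write_metabolome(mat, f, layout = "long")
  rt <- read_metabolome(f, layout = "long")
  expect_true(is.na(rt$values[2, 3]))
  expect_equal(sum(is.na(rt$values)), 1)
})

test_that("malformed inputs are rejected with the offender named", {
  mat <- tiny_matrix()
  f <- withr::local_tempfile(fileext = ".csv")

  # negative intensity names the cell
  bad <- mat
  bad$values[1, 2] <- -1
  tab <- cbind(as.data.frame(bad$samples), as.data.frame(bad$values))
  write.csv(tab, f, row.names = FALSE)
  expect_error(read_metabolome(f, "wide"), "negative intensity.*m02")

  # duplicate cell in long layout
  write_metabolome(mat, f, layout = "long")
  tab <- read.csv(f)
  write.csv(rbind(tab, tab[1, ]), f, row.names = FALSE)
  expect_error(read_metabolome(f, "long"), "duplicate cell")

  # missing metadata column
  tab <- cbind(as.data.frame(mat$samples), as.data.frame(mat$values))
  tab$replicate <- NULL
  write.csv(tab, f, row.names = FALSE)
  expect_error(read_metabolome(f, "wide"), "replicate")

  # duplicate design triple
  smp <- as.data.frame(mat$samples)
  smp$replicate[2] <- smp$replicate[1]
  smp$sample_id[2] <- "other"
  expect_error(metabolome_matrix(mat$values, smp, mat$metabolites),
               "duplicate \\(variety")
})

test_that("tab-delimited input is auto-detected", {
  mat <- tiny_matrix(n_met = 3)
  f <- withr::local_tempfile(fileext = ".tsv")
  tab <- cbind(as.data.frame(mat$samples), as.data.frame(mat$values))
  write.table(tab, f, sep = "\t", row.names = FALSE, quote = FALSE)
  rt <- read_metabolome(f, "wide")
  expect_equal(rt$values, mat$values, tolerance = 1e-9)
})

test_that("phenotype validation warns but does not fail on soft violations", {
  ph <- data.frame(variety = "A", timepoint_hai = c(0, 6, 12),
                   germination_fraction = c(0.2, 0.5, 0.4))
  expect_warning(validate_phenotype(ph), "decreases")
  ph$germination_fraction <- c(0.2, 0.5, 1.5)
  expect_error(validate_phenotype(ph), "outside")
  ph2 <- data.frame(variety = "A", timepoint_hai = 0,
                    germination_fraction = 0,
                    fresh_weight = 0.2, dry_weight = 0.25)
  expect_warning(validate_phenotype(ph2), "fresh_weight")
})

test_that("network export writes edge/node tables that round-trip", {
  pre <- file.path(withr::local_tempdir(), "net")

  # empty edge set still yields a valid header-only table
  empty <- tibble::tibble(metabolite_id = character(),
                          variety = character(), r = numeric())
  write_network(empty, out_prefix = pre, formats = "csv")
  rt <- read_network_edges(pre)
  expect_equal(nrow(rt), 0)
  expect_true(all(c("source", "target", "weight", "sign") %in% names(rt)))

  # one edge carries its weight
  one <- tibble::tibble(metabolite_id = "metA", variety = "V", r = 0.9)
  write_network(one, out_prefix = pre)
  rt <- read_network_edges(pre)
  expect_equal(rt$weight, 0.9)
  expect_equal(rt$target, "germination_rate_V")
  expect_equal(rt$sign, "positive")

  # row count contract at the published network size
  n <- 184
  edges <- tibble::tibble(metabolite_id = sprintf("M%03d", seq_len(n)),
                          variety = rep(c("A", "B"), length.out = n),
                          r = seq(-1, 1, length.out = n))
  files <- write_network(edges, out_prefix = pre)
  rt <- read_network_edges(pre)
  expect_equal(nrow(rt), n)
  expect_equal(rt$weight, edges$r, tolerance = 1e-12)

  # sif and graphml mirrors exist and are loadable
  expect_true(file.exists(paste0(pre, ".sif")))
  expect_equal(length(readLines(paste0(pre, ".sif"))), n)
  g <- igraph::read_graph(paste0(pre, ".graphml"), format = "graphml")
  expect_equal(igraph::ecount(g), n)
})

test_that("flagged rows are dropped before network export", {
  edges <- tibble::tibble(metabolite_id = c("a", "b"), variety = "V",
                          r = c(0.9, 0.5), passes = c(TRUE, FALSE))
  pre <- file.path(withr::local_tempdir(), "net")
  write_network(edges, out_prefix = pre, formats = "csv")
  expect_equal(nrow(read_network_edges(pre)), 1)
})
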