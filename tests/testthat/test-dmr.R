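meth_track <- function(pos, delta, base = 50) {
  tibble::tibble(chrom = "1", pos = pos, pct_a = base, pct_b = base + delta)
}

test_that("intergenic flank regions span neighbor gene bodies", {
  ann <- tibble::tibble(
    gene_id = c("left", "mid", "right"), chrom = "1",
    start = c(100, 1000, 3000), end = c(400, 2000, 3500), strand = "+")
  r <- flank_region("mid", ann)
  expect_equal(c(r$start, r$end), c(400, 3000))
  # no left neighbor -> region starts at position 1
  r2 <- flank_region("left", ann)
  expect_equal(r2$start, 1)
  expect_equal(r2$end, 1000)
  # no right neighbor: chromosome length when known, open otherwise
  expect_equal(flank_region("right", ann)$end, Inf)
  expect_equal(flank_region("right", ann, chrom_lengths = c("1" = 9000))$end,
               9000)
  # immediately adjacent neighbors leave zero-length flanks
  tight <- tibble::tibble(
    gene_id = c("l", "g", "r"), chrom = "1",
    start = c(100, 400, 2000), end = c(400, 2000, 2600), strand = "+")
  rt <- flank_region("g", tight)
  expect_equal(c(rt$start, rt$end), c(400, 2000))
  # overlapping neighbor truncates with a warning
  over <- tibble::tibble(
    gene_id = c("o", "g"), chrom = "1",
    start = c(100, 400), end = c(600, 2000), strand = "+")
  expect_warning(ro <- flank_region("g", over), "truncated")
  expect_equal(ro$start, 400)
  expect_error(flank_region("absent", ann), "not found")
})

test_that("identical methylation tracks yield no DMR", {
  rec <- meth_track(seq(100, 2000, by = 50), delta = 0)
  expect_equal(nrow(find_dmrs(rec)), 0)
})

test_that("clustered differential cytosines chain into a single DMR", {
  pos <- c(100, 110, 120, 130, 140, 150)
  rec <- meth_track(pos, delta = 40)
  d <- find_dmrs(rec, min_diff = 20, min_count = 5, max_gap = 100)
  expect_equal(nrow(d), 1)
  expect_equal(c(d$start, d$end), c(100, 150))
  expect_equal(d$n_cytosines, 6L)
  expect_equal(d$n_hyper_b, 6L)
  expect_equal(d$mean_difference, 40)
})

test_that("a gap beyond max_gap splits a chain below min_count", {
  pos <- c(100, 120, 140, 1000, 1020)
  rec <- meth_track(pos, delta = 40)
  expect_equal(nrow(find_dmrs(rec, min_diff = 20, min_count = 5,
                              max_gap = 100)), 0)
  # merging the gap recovers one region of five
  d <- find_dmrs(rec, min_diff = 20, min_count = 5, max_gap = 900)
  expect_equal(nrow(d), 1)
  expect_equal(d$n_differential, 5L)
})

test_that("hypomethylation in condition B is differential but not hyper", {
  rec <- meth_track(seq(100, 150, by = 10), delta = -40)
  d <- find_dmrs(rec, min_diff = 20, min_count = 5, max_gap = 100)
  expect_equal(nrow(d), 1)
  expect_equal(d$n_hyper_b, 0L)
  expect_lt(d$mean_difference, 0)
})

test_that("interval counts include non-differential cytosines inside the DMR", {
  rec <- dplyr::bind_rows(
    meth_track(c(100, 120, 140, 160, 180), delta = 40),
    meth_track(c(130, 150), delta = 0)
  ) |> dplyr::arrange(pos)
  d <- find_dmrs(rec, min_diff = 20, min_count = 5, max_gap = 100)
  expect_equal(d$n_cytosines, 7L)
  expect_equal(d$n_differential, 5L)
  expect_equal(d$n_hyper_b, 5L)
})

test_that("unsorted input is rejected and empty input returns empty", {
  rec <- meth_track(c(200, 100), delta = 40)
  expect_error(find_dmrs(rec), "sorted")
  expect_equal(nrow(find_dmrs(meth_track(numeric(0), numeric(0)))), 0)
  expect_error(find_dmrs(meth_track(100, delta = 80)), "0, 100")
})

test_that("DMR calls agree with brute-force chain enumeration", {
  set.seed(14)
  for (rep in 1:40) {
    n <- sample(5:80, 1)
    pos <- sort(sample.int(3000, n))
    delta <- sample(c(0, 10, 25, 40, -30), n, replace = TRUE)
    rec <- meth_track(pos, delta)
    params <- list(min_diff = sample(c(15, 20, 30), 1),
                   min_count = sample(2:5, 1),
                   max_gap = sample(c(50, 150, 400), 1))
    got <- find_dmrs(rec, params$min_diff, params$min_count, params$max_gap)
    want <- oracle_dmrs(rec, params$min_diff, params$min_count,
                        params$max_gap)
    expect_equal(nrow(got), nrow(want))
    if (nrow(got) > 0) {
      expect_equal(got$start, want$start)
      expect_equal(got$end, want$end)
    }
  }
})

test_that("stricter thresholds never add DMRs; larger gaps never drop coverage", {
  sim <- simulate_methylation(
    n_background = 200, seed = 9,
    dmrs = list(list(start = 3000, width = 300, n_cytosines = 8, effect = 40),
                list(start = 9000, width = 300, n_cytosines = 6, effect = 40)))
  rec <- sim$records
  for (mg in c(100, 250)) {
    n_prev <- Inf
    for (md in c(10, 20, 35, 45)) {
      n <- nrow(find_dmrs(rec, min_diff = md, min_count = 4, max_gap = mg))
      expect_lte(n, n_prev)
      n_prev <- n
    }
    n_prev <- Inf
    for (mc in c(2, 4, 6, 9)) {
      n <- nrow(find_dmrs(rec, min_diff = 20, min_count = mc, max_gap = mg))
      expect_lte(n, n_prev)
      n_prev <- n
    }
  }
  covered <- function(mg) {
    d <- find_dmrs(rec, min_diff = 20, min_count = 2, max_gap = mg)
    sum(d$n_differential)
  }
  expect_lte(covered(50), covered(250))
  expect_lte(covered(250), covered(2000))
})

test_that("DMRs are oriented and distanced relative to the gene strand", {
  gene_plus <- tibble::tibble(gene_id = "g", chrom = "1", start = 5000,
                              end = 6000, strand = "+")
  gene_minus <- dplyr::mutate(gene_plus, strand = "-")
  rec <- dplyr::bind_rows(
    meth_track(seq(3000, 3080, by = 20), delta = 40),   # left of the gene
    meth_track(seq(6432 + 6000, 6432 + 6080, by = 20), delta = 40)  # right
  )
  d_plus <- find_dmrs(rec, gene = gene_plus)
  expect_equal(d_plus$side, c("upstream", "downstream"))
  expect_equal(d_plus$distance, c(5000 - 3080, 6432))
  d_minus <- find_dmrs(rec, gene = gene_minus)
  expect_equal(d_minus$side, c("downstream", "upstream"))
  # a DMR overlapping the gene body sits at distance zero
  inside <- meth_track(seq(5100, 5180, by = 20), delta = 40)
  d_in <- find_dmrs(inside, gene = gene_plus)
  expect_equal(d_in$side, "overlapping")
  expect_equal(d_in$distance, 0)
})
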