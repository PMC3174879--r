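# Hand-built allele tables over the standard 4-sample x 3-timepoint design.
poo_design <- function() cross_design(c("A", "B"), c(3, 4, 5))

# presence named by sample label; unnamed samples default to absent
poo_table <- function(..., design = poo_design()) {
  cells <- list(...)
  row <- tibble::tibble(primer_key = "BstYI+TCC/MseI+AG", bin_center = 120)
  for (s in design$sample) {
    row[[s]] <- if (s %in% names(cells)) as.integer(cells[[s]]) else 0L
  }
  row
}

self_present <- function(acc, tps = c(3, 4, 5)) {
  stats::setNames(as.list(rep(1L, length(tps))),
                  sprintf("%sx%s_%gdap", acc, acc, tps))
}

test_that("polymorphism requires consistent presence in exactly one self", {
  d <- poo_design()
  tab <- do.call(poo_table, self_present("A"))
  expect_true(detect_polymorphic(tab, d)$polymorphic)
  expect_equal(detect_polymorphic(tab, d)$carrier, "A")

  both <- do.call(poo_table, c(self_present("A"), self_present("B")))
  expect_false(detect_polymorphic(both, d)$polymorphic)

  nowhere <- poo_table()
  expect_false(detect_polymorphic(nowhere, d)$polymorphic)

  # inconsistent across timepoints in the carrier self -> not polymorphic
  flicker <- do.call(poo_table, self_present("A", c(3, 4)))
  expect_false(detect_polymorphic(flicker, d)$polymorphic)
})

test_that("missing self samples raise an error naming the absent cross", {
  d <- poo_design()
  d_noself <- d[!(d$mother == "B" & d$father == "B"), ]
  tab <- do.call(poo_table, c(self_present("A"), list(design = d_noself)))
  expect_error(detect_polymorphic(tab, d_noself), "B x B")
  # table lacking a design sample column is also named
  tab2 <- do.call(poo_table, self_present("A"))
  tab2$`AxB_3dap` <- NULL
  expect_error(detect_polymorphic(tab2, d), "AxB_3dap")
})

test_that("maternal calls need >= min_stages supporting timepoints and no opposition", {
  d <- poo_design()
  # carrier A; maternal pattern at 3 and 4 dap
  tab <- do.call(poo_table, c(self_present("A"),
                              list(AxB_3dap = 1, AxB_4dap = 1)))
  call <- call_parent_of_origin(tab, d)
  expect_equal(call$call, "maternal")
  expect_equal(call$supporting_timepoints, "3,4")
  expect_equal(call$n_support, 2L)

  # mirror pattern: carrier expressed only when inherited from the father
  pat <- do.call(poo_table, c(self_present("A"),
                              list(BxA_3dap = 1, BxA_5dap = 1)))
  expect_equal(call_parent_of_origin(pat, d)$call, "paternal")

  # present in both F1 directions at all timepoints -> biallelic pattern
  bi <- do.call(poo_table, c(self_present("A"),
                             list(AxB_3dap = 1, AxB_4dap = 1, AxB_5dap = 1,
                                  BxA_3dap = 1, BxA_4dap = 1, BxA_5dap = 1)))
  expect_equal(call_parent_of_origin(bi, d)$call, "not_uniparental")

  # mixed maternal and paternal support -> not uniparental
  mixed <- do.call(poo_table, c(self_present("A"),
                                list(AxB_3dap = 1, BxA_4dap = 1)))
  expect_equal(call_parent_of_origin(mixed, d)$call, "not_uniparental")

  # maternal pattern at a single stage, silent otherwise -> below threshold
  one <- do.call(poo_table, c(self_present("A"), list(AxB_4dap = 1)))
  expect_equal(call_parent_of_origin(one, d)$call, "insufficient_evidence")

  # non-polymorphic rows pass through unchanged
  both <- do.call(poo_table, c(self_present("A"), self_present("B")))
  expect_equal(call_parent_of_origin(both, d)$call, "not_polymorphic")
})

test_that("timepoints with missing samples are uninformative, not contradictory", {
  d <- poo_design()
  d_cut <- d[!(d$sample == "BxA_5dap"), ]
  # maternal at 3 and 4; 5 dap cannot be evaluated without the reciprocal
  tab <- do.call(poo_table, c(self_present("A"),
                              list(AxB_3dap = 1, AxB_4dap = 1, AxB_5dap = 1,
                                   design = d_cut)))
  call <- call_parent_of_origin(tab, d_cut)
  expect_equal(call$call, "maternal")
  expect_equal(call$supporting_timepoints, "3,4")
})

test_that("swapping accession labels converts the carrier but never flips the call", {
  sim <- simulate_transcriptome(n_genes = 60, seed = 11)
  at <- simulate_allele_table(sim$truth, accessions = c("A", "B"), seed = 12)
  calls <- call_parent_of_origin(at$table, at$design)

  # relabel A<->B everywhere: sample columns and design rows
  swap <- function(x) chartr("AB", "BA", x)
  tab2 <- at$table
  names(tab2) <- ifelse(names(tab2) %in% at$design$sample,
                        swap(names(tab2)), names(tab2))
  design2 <- at$design
  design2$sample <- swap(design2$sample)
  design2$mother <- swap(design2$mother)
  design2$father <- swap(design2$father)
  calls2 <- call_parent_of_origin(tab2, design2)

  expect_equal(calls2$call, calls$call)
  poly <- calls$polymorphic
  expect_equal(calls2$carrier[poly], swap(calls$carrier[poly]))
})

test_that("every TDF receives exactly one call category", {
  sim <- simulate_transcriptome(n_genes = 80, seed = 21)
  at <- simulate_allele_table(sim$truth, seed = 22, maternal_fraction = 0.6)
  calls <- call_parent_of_origin(at$table, at$design)
  expect_equal(nrow(calls), nrow(at$table))
  expect_true(all(calls$call %in% c("maternal", "paternal", "not_uniparental",
                                    "not_polymorphic",
                                    "insufficient_evidence")))
  # polymorphic TDFs never land in the not_polymorphic bucket and vice versa
  expect_equal(calls$call == "not_polymorphic", !calls$polymorphic)
})

test_that("capillary sizes bin to the nearest center within the half width", {
  expect_equal(assign_bins(c(100.3, 101.2, 150, 125.4), c(100, 150)),
               c(1L, NA_integer_, 2L, NA_integer_))
  # overlapping candidate bins resolve to the nearest center
  expect_equal(assign_bins(100.6, c(100, 101), half_width = 0.8), 2L)
  expect_equal(assign_bins(100.4, c(100, 101), half_width = 0.8), 1L)
})
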