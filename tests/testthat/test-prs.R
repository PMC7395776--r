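make_toy_panel <- function() {
  weight_panel(data.frame(
    variant_id = c("rs1", "rs2", "rs3"),
    chr = 1, pos = 1:3,
    effect_allele = c("A", "C", "G"),
    other_allele = c("G", "T", "A"),
    weight_overall = c(0.1, -0.2, 0.05),
    weight_erpos = c(0.12, -0.25, 0.06),
    weight_erneg = c(0.08, -0.15, 0.04),
    info = c(1, 0.95, 0.92),
    freq_pop1 = c(0.3, 0.2, 0.4),
    freq_pop2 = c(0.25, 0.02, 0.35),
    stringsAsFactors = FALSE
  ))
}

make_toy_dosages <- function(panel, flip = integer(0)) {
  X <- matrix(c(0, 1, 2,
                2, 0, 1), nrow = 2, byrow = TRUE)
  info <- data.frame(variant_id = panel$variant_id,
                     counted_allele = panel$effect_allele,
                     other_allele = panel$other_allele,
                     stringsAsFactors = FALSE)
  for (j in flip) {
    info[j, c("counted_allele", "other_allele")] <-
      info[j, c("other_allele", "counted_allele")]
    X[, j] <- 2 - X[, j]
  }
  dosage_matrix(X, info, sample_ids = c("i1", "i2"))
}

test_that("weight files round-trip bit-exactly and reject malformed input", {
  panel <- gen_weight_panel(sim_config(n_snps = 20, n_low_info = 3, seed = 4))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_weight_panel(panel, path)
  back <- read_weight_panel(path)
  for (col in names(panel)) expect_identical(back[[col]], panel[[col]],
                                             label = col)

  dup <- as.data.frame(panel)[c(1, 1, 2), ]
  expect_error(weight_panel(dup), dup$variant_id[1])
  expect_error(weight_panel(panel[, setdiff(names(panel), "weight_overall")]),
               "weight_overall")
  bad <- as.data.frame(panel)
  bad$weight_overall[3] <- NaN
  expect_error(weight_panel(bad), "non-finite")
  same <- as.data.frame(panel)
  same$other_allele <- same$effect_allele
  expect_error(weight_panel(same), "equals")
})

test_that("INFO filtering retains exactly the qualifying variants in order", {
  panel <- make_toy_panel()
  expect_identical(filter_by_info(panel, 0), panel)
  expect_identical(filter_by_info(panel, 0.93)$variant_id, c("rs1", "rs2"))
  all_one <- panel
  all_one$info <- rep(1, 3)
  expect_identical(filter_by_info(all_one, 1), all_one)
  expect_equal(nrow(filter_by_info(panel, 0.99)), 1)
})

test_that("restriction to available variants drops missing and monomorphic SNPs", {
  panel <- make_toy_panel()
  dos <- make_toy_dosages(panel)
  expect_identical(restrict_to_available(panel, dos), panel)

  # dosage source carrying a subset
  sub <- dosage_matrix(unclass(dos)[, 1:2],
                       attr(dos, "variant_info")[1:2, ],
                       sample_ids = rownames(dos))
  expect_identical(restrict_to_available(panel, sub)$variant_id,
                   c("rs1", "rs2"))

  # monomorphic column is dropped even though present
  X <- unclass(dos)
  X[, 2] <- 1
  mono <- dosage_matrix(X, attr(dos, "variant_info"),
                        sample_ids = rownames(dos))
  expect_identical(restrict_to_available(panel, mono)$variant_id,
                   c("rs1", "rs3"))

  other <- dosage_matrix(matrix(1:4 / 2, 2),
                         data.frame(variant_id = c("rsX", "rsY"),
                                    counted_allele = "A", other_allele = "C"))
  expect_error(restrict_to_available(panel, other), "no panel variant")

  # a large panel against a source carrying 229 of 287 variants
  big <- gen_weight_panel(sim_config(n_snps = 313, n_low_info = 26, seed = 6))
  kept <- filter_by_info(big, 0.9)
  expect_equal(nrow(kept), 287)
  idx <- seq_len(229)
  src <- dosage_matrix(
    matrix(rep(c(0, 1, 2), length.out = 3 * 229), nrow = 3),
    data.frame(variant_id = kept$variant_id[idx],
               counted_allele = kept$effect_allele[idx],
               other_allele = kept$other_allele[idx]))
  expect_equal(nrow(restrict_to_available(kept, src)), 229)
})

test_that("PRS computation matches hand values and the brute-force oracle", {
  panel <- make_toy_panel()
  zero <- panel
  zero$weight_overall <- rep(0, 3)
  dos <- make_toy_dosages(panel)
  expect_equal(unname(compute_prs(dos, zero)), c(0, 0))

  one_snp <- panel[1, ]
  d1 <- dosage_matrix(matrix(c(0, 1, 2), 3),
                      data.frame(variant_id = "rs1", counted_allele = "A",
                                 other_allele = "G"))
  expect_equal(unname(compute_prs(d1, one_snp)), c(0, 0.1, 0.2))

  flipped <- make_toy_dosages(panel, flip = 2)
  expect_equal(unname(compute_prs(flipped, panel)),
               brute_prs(flipped, panel))
  expect_equal(unname(compute_prs(flipped, panel, "erpos")),
               brute_prs(flipped, panel, "weight_erpos"))
})

test_that("scores are invariant to allele flips and linear in the weights", {
  panel <- gen_weight_panel(sim_config(n_snps = 30, seed = 9))
  set.seed(10)
  X <- matrix(rbinom(25 * 30, 2, 0.4), 25, 30)
  info <- data.frame(variant_id = panel$variant_id,
                     counted_allele = panel$effect_allele,
                     other_allele = panel$other_allele)
  dos <- dosage_matrix(X, info)
  base <- compute_prs(dos, panel)

  flip_cols <- sample(30, 12)
  X2 <- X
  info2 <- info
  for (j in flip_cols) {
    X2[, j] <- 2 - X2[, j]
    info2[j, c("counted_allele", "other_allele")] <-
      info2[j, c("other_allele", "counted_allele")]
  }
  expect_equal(compute_prs(dosage_matrix(X2, info2), panel), base)

  p1 <- panel; p2 <- panel; psum <- panel
  set.seed(11)
  p2$weight_overall <- rnorm(30, sd = 0.05)
  psum$weight_overall <- p1$weight_overall + p2$weight_overall
  expect_equal(compute_prs(dos, psum),
               compute_prs(dos, p1) + compute_prs(dos, p2))

  # filter composition is order-independent
  a <- restrict_to_available(filter_by_info(panel, 0.9), dos)
  b <- filter_by_info(restrict_to_available(panel, dos), 0.9)
  expect_identical(a, b)
})

test_that("scoring rejects unresolvable variants and allele mismatches", {
  panel <- make_toy_panel()
  dos <- make_toy_dosages(panel)
  extra <- weight_panel(rbind(as.data.frame(panel),
                              within(as.data.frame(panel)[1, ], {
                                variant_id <- "rs99"
                              })))
  expect_error(compute_prs(dos, extra), "rs99")

  info <- attr(dos, "variant_info")
  info$counted_allele[2] <- "G"  # neither panel orientation for rs2 (C/T)
  bad <- dosage_matrix(unclass(dos), info, sample_ids = rownames(dos))
  expect_error(compute_prs(bad, panel), "rs2")

  # missing dosages: hard error by default, 2*frequency under impute mode
  X <- unclass(dos)
  X[1, 2] <- NA
  holey <- dosage_matrix(X, attr(dos, "variant_info"),
                         sample_ids = rownames(dos))
  expect_error(compute_prs(holey, panel), "missing dosage")
  imp <- compute_prs(holey, panel, missing = "impute")
  X[1, 2] <- 2 * panel$freq_pop2[2]
  filled <- dosage_matrix(X, attr(dos, "variant_info"),
                          sample_ids = rownames(dos))
  expect_equal(imp, compute_prs(filled, panel))
})

test_that("standardisation divides by the reference SD and nothing else", {
  raw <- c(a = 0.3, b = 0.9, c = 1.5)
  expect_equal(standardize_prs(raw, 1)$standardized_value, unname(raw))
  own <- standardize_prs(raw, sd(raw))
  expect_equal(sd(own$standardized_value), 1)
  expect_equal(own$standardized_value * own$reference_sd, unname(raw))
  expect_equal(mean(standardize_prs(rep(0.91, 5), 0.597)$standardized_value),
               1.524, tolerance = 5e-4)
  expect_error(standardize_prs(raw, 0), "positive")
  expect_error(standardize_prs(raw, -1), "positive")
})

test_that("PRS summaries report n, mean and unbiased SD per group", {
  expect_equal(summarize_prs(rep(2, 4), rep("g", 4))$sd, 0)
  s <- summarize_prs(c(1, 2, 3), rep("g", 3))
  expect_equal(s$mean, 2)
  expect_equal(s$sd, 1)
  expect_error(summarize_prs(1:3, c("a", "b", "b")), "at least 2")

  cfg <- sim_config(n_cases = 3000, n_controls = 10000, seed = 12)
  sc <- make_scored_cohort(cfg)
  ctrl <- summarize_prs(sc$cohort$prs_raw, sc$cohort$status)
  sd_ctrl <- ctrl$sd[ctrl$group == "0"]
  expect_lt(abs(sd_ctrl - 0.556) / 0.556, 0.02)
})

test_that("dosage matrices round-trip through TSV and VCF", {
  panel <- make_toy_panel()
  dos <- make_toy_dosages(panel, flip = 3)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_dosage_tsv(dos, tsv)
  back <- read_dosage_tsv(tsv)
  expect_equal(unclass(back)[, ], unclass(dos)[, ], ignore_attr = TRUE)
  expect_equal(attr(back, "variant_info"), attr(dos, "variant_info"))

  vcf <- withr::local_tempfile(fileext = ".vcf")
  write_dosage_vcf(dos, vcf)
  vback <- read_dosage_vcf(vcf)
  expect_equal(unclass(vback)[, ], unclass(dos)[, ], ignore_attr = TRUE)
  expect_equal(attr(vback, "variant_info")$counted_allele,
               attr(dos, "variant_info")$counted_allele)
  expect_equal(unname(compute_prs(vback, panel)),
               unname(compute_prs(dos, panel)))
})
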