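test_that("enzyme-site counting handles strands and overlap as specified", {
  expect_equal(count_enzyme_sites("ATATAT"), 0)
  expect_equal(count_enzyme_sites("AACCGCTT"), 1)
  expect_equal(count_enzyme_sites("AAGCGGTT"), 1)   # site on the other strand
  expect_equal(count_enzyme_sites("AAGCGGTT", count_both_strands = FALSE), 0)
  expect_equal(count_enzyme_sites("CCGCCGC"), 2)    # overlap at 0 and 3
  expect_equal(count_enzyme_sites("CCGCCGC", allow_overlap = FALSE), 1)
  expect_error(count_enzyme_sites("ACGU"), "position")
})

test_that("site counts equal the sliding-window oracle on random sequences", {
  set.seed(202)
  for (i in 1:300) {
    s <- random_dna(sample(20:200, 1))
    expect_identical(count_enzyme_sites(s), count_sites_window(s))
  }
  # GC-rich sequences stress the overlapping-match path
  for (i in 1:100) {
    s <- paste(sample(c("C", "G"), 60, TRUE, prob = c(0.6, 0.4)),
               collapse = "")
    expect_identical(count_enzyme_sites(s), count_sites_window(s))
  }
})

test_that("amplicon validation enforces primers, roles and fragmentation sites", {
  fwd <- "ACTGACTGACTGACTGAATT"; rev <- "TTCATTCATTCATTCATTCA"
  six <- make_amplicon_with_sites(6, fwd, rev)
  spec <- amplicon_spec("asat_msre", six, fwd, rev, role = "msre_target")
  rep <- validate_amplicon(spec)
  expect_true(attr(rep, "valid"))
  expect_equal(attr(rep, "n_sites"), 6)
  # a control amplicon containing one site fails its role check
  bad_ctrl <- amplicon_spec("asat_ctrl", make_amplicon_with_sites(1, fwd, rev),
                            fwd, rev, role = "msre_control")
  repc <- validate_amplicon(bad_ctrl)
  expect_false(attr(repc, "valid"))
  expect_false(repc$pass[repc$check == "enzyme_sites_match_role"])
  good_ctrl <- amplicon_spec("asat_ctrl", make_amplicon_with_sites(0, fwd, rev),
                             fwd, rev, role = "msre_control")
  expect_true(attr(validate_amplicon(good_ctrl), "valid"))
  # absent primer is reported by name
  repp <- validate_amplicon(amplicon_spec("x", six, "AAAAAAAA", rev,
                                          role = "msre_target"))
  expect_false(repp$pass[repp$check == "forward_primer_present"])
  expect_match(repp$detail[repp$check == "forward_primer_present"], "AAAAAAAA")
  # an internal XbaI site invalidates the design
  with_xba <- amplicon_spec("x", paste0(fwd, "TCTAGA",
                                        substring(six, nchar(fwd) + 1)),
                            fwd, rev, role = "msre_target")
  repx <- validate_amplicon(with_xba)
  expect_false(repx$pass[repx$check == "no_internal_fragmentation_site"])
})

test_that("relative methylation follows efficiency^-dCt with Ct averaged first", {
  ct <- tidyr::expand_grid(condition = "c", biological_repeat = 1L,
                           technical_replicate = 1:2,
                           primer_role = c("msre_target", "msre_control"))
  ct$ct <- 24
  ct$ct[ct$primer_role == "msre_target"] <- c(25, 27)  # asymmetric tech reps
  est <- msre_relative_methylation(ct)
  expect_equal(est$delta_ct, 2)                    # mean Ct first: (25+27)/2-24
  expect_equal(est$relative_methylation, 2^-2)
  # averaging after exponentiation would give (2^-1 + 2^-3)/2 = 0.3125
  expect_false(isTRUE(all.equal(est$relative_methylation, 0.3125)))
  # closed-form anchors
  anchors <- tibble::tibble(dct = c(0, 1, log2(10)), rel = c(1, 0.5, 0.1))
  for (i in seq_len(nrow(anchors))) {
    ct2 <- tibble::tibble(condition = "c", biological_repeat = 1L,
                          technical_replicate = 1L,
                          primer_role = c("msre_target", "msre_control"),
                          ct = c(24 + anchors$dct[i], 24))
    expect_equal(msre_relative_methylation(ct2)$relative_methylation,
                 anchors$rel[i], tolerance = 1e-12)
  }
})

test_that("undetermined targets are flagged below detection; missing control errors", {
  ct <- tibble::tibble(condition = "c", biological_repeat = 1L,
                       technical_replicate = 1L,
                       primer_role = c("msre_target", "msre_control"),
                       ct = c(NA, 24), undetermined = c(TRUE, FALSE))
  est <- msre_relative_methylation(ct)
  expect_true(est$below_detection)
  expect_true(is.na(est$relative_methylation))
  expect_error(msre_relative_methylation(ct[ct$primer_role != "msre_control", ]),
               "msre_control")
})

test_that("relative methylation decreases in dCt and fold change in ddCt", {
  dcts <- seq(-2, 4, by = 0.5)
  rels <- vapply(dcts, function(d) {
    ct <- tibble::tibble(condition = "c", biological_repeat = 1L,
                         technical_replicate = 1L,
                         primer_role = c("msre_target", "msre_control"),
                         ct = c(24 + d, 24))
    msre_relative_methylation(ct)$relative_methylation
  }, 0)
  expect_true(all(diff(rels) < 0))
})

test_that("delta-delta-Ct expression matches closed forms incl. efficiency correction", {
  make_ct <- function(target_ref, target_cond, E_label = NULL) {
    tibble::tibble(condition = rep(c("ref", "cond"), each = 2),
                   biological_repeat = 1L, technical_replicate = 1L,
                   primer_role = rep(c("expr_target", "expr_reference"), 2),
                   ct = c(target_ref, 18, target_cond, 18))
  }
  # identical dCt both conditions -> fold 1
  est <- ddct_expression(make_ct(28, 28), reference_condition = "ref")
  expect_equal(est$fold_change[est$condition == "cond"], 1)
  # ddCt = -1 -> fold 2 at E = 2; 1.9 at E = 1.9
  est2 <- ddct_expression(make_ct(28, 27), reference_condition = "ref")
  expect_equal(est2$fold_change[est2$condition == "cond"], 2)
  est3 <- ddct_expression(make_ct(28, 27), efficiency = 1.9,
                          reference_condition = "ref")
  expect_equal(est3$fold_change[est3$condition == "cond"], 1.9)
})

test_that("the simulated expression assay round-trips the true fold change", {
  conds <- tibble::tibble(condition = c("mock", "aza"),
                          methylated_fraction = c(0.8, 0.4),
                          expression_fold = c(1, 2))
  cfg <- qpcr_sim_config(conds, technical_sd = 0.15, n_technical = 3,
                         n_biological = 50, seed = 31)
  plate <- simulate_qpcr_plate(cfg, assay = "expression")
  est <- ddct_expression(plate, reference_condition = "mock")
  expect_equal(mean(est$fold_change[est$condition == "aza"]), 2,
               tolerance = 0.05)
})
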