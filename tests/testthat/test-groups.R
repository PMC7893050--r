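test_that("sites are pooled into classes under the boundary convention", {
  sp <- ligand_spectrum(c(4.2, 5.6), c(0.05, 0.06))
  tot <- bin_functional_groups(sp)
  expect_equal(unname(tot["carboxyl"]), 0.11)
  expect_equal(unname(tot[c("phosphoryl", "amine", "hydroxyl", "unassigned")]),
               rep(0, 4))

  # boundary sites: 5.8 carboxyl (gap above), 6 phosphoryl, 8 amine,
  # 9 and 10 hydroxyl
  sp2 <- ligand_spectrum(c(5.8, 6.0, 8.0, 9.0, 10.0), rep(1, 5))
  tot2 <- bin_functional_groups(sp2)
  expect_equal(unname(tot2[c("carboxyl", "phosphoryl", "amine", "hydroxyl")]),
               c(1, 1, 1, 2))

  # hand assignment: 6.0 phosphoryl; 9.0 and 10.0 hydroxyl
  sp3 <- ligand_spectrum(c(6.0, 9.0, 10.0), c(0.1, 0.2, 0.05))
  tot3 <- bin_functional_groups(sp3)
  expect_equal(unname(tot3["phosphoryl"]), 0.1)
  expect_equal(unname(tot3["hydroxyl"]), 0.25)

  # a site in the 5.8-6 gap is reported as unassigned, never dropped
  sp4 <- ligand_spectrum(5.9, 0.3)
  expect_equal(unname(bin_functional_groups(sp4)["unassigned"]), 0.3)
})

test_that("class totals plus unassigned reproduce the spectrum total exactly", {
  set.seed(41)
  for (k in 1:20) {
    ns <- sample(1:8, 1)
    sp <- ligand_spectrum(runif(ns, 2.5, 11), runif(ns, 0, 1e-3))
    tot <- bin_functional_groups(sp)
    expect_equal(sum(tot), sp$total_LT, tolerance = 1e-14)
  }
})

test_that("binning is invariant to site order and to within-class mass trades", {
  scheme <- functional_group_scheme()
  sp <- ligand_spectrum(c(4.2, 5.0, 7.0, 8.4), c(1e-4, 2e-4, 3e-4, 4e-4))
  perm <- ligand_spectrum(c(8.4, 4.2, 7.0, 5.0), c(4e-4, 1e-4, 3e-4, 2e-4))
  expect_equal(bin_functional_groups(sp, scheme),
               bin_functional_groups(perm, scheme))
  # move mass between two carboxyl sites: class totals unchanged
  traded <- ligand_spectrum(c(4.2, 5.0, 7.0, 8.4), c(2.5e-4, 0.5e-4, 3e-4, 4e-4))
  expect_equal(bin_functional_groups(sp, scheme),
               bin_functional_groups(traded, scheme))
})

test_that("overlapping class schemes are rejected", {
  bad <- data.frame(name = c("a", "b"), lo = c(3, 5), hi = c(6, 8))
  expect_error(functional_group_scheme(bad), "overlap")
})

test_that("replicate aggregation reports mean and n-1 standard deviation", {
  s1 <- aggregate_replicates(list(c(carboxyl = 0.1), c(carboxyl = 0.1),
                                  c(carboxyl = 0.1)))
  expect_equal(s1$mean, 0.1)
  expect_equal(s1$sd, 0)

  s2 <- aggregate_replicates(list(c(carboxyl = 0.2), c(carboxyl = 0.4),
                                  c(carboxyl = 0.6)))
  expect_equal(s2$mean, 0.4)
  expect_equal(s2$sd, 0.2)
  expect_equal(s2$n_replicates, 3)

  s3 <- aggregate_replicates(list(c(carboxyl = 0.3)))
  expect_equal(s3$mean, 0.3)
  expect_true(is.na(s3$sd))

  expect_error(aggregate_replicates(list(c(a = 1), c(b = 1))), "inconsistent")
})

test_that("the rendered table follows the reporting layout", {
  reps <- list(c(carboxyl = 0.113, phosphoryl = 0.149, amine = 0.845,
                 hydroxyl = 0, unassigned = 0))
  s <- aggregate_replicates(list(reps[[1]], reps[[1]] + 0.01, reps[[1]] - 0.01))
  rep1 <- render_table1_report(list("KAAS-1 March" = s),
                               input_units = "mmol_per_g")
  expect_equal(names(rep1)[1:2], c("Functional Group", "pKa Range"))
  expect_equal(rep1[["pKa Range"]][1], "3–5.8")
  expect_match(rep1[[3]][1], "^0\\.113 ± 0\\.010$")

  # empty class renders as zeros; two samples give two value columns
  s0 <- aggregate_replicates(list(c(carboxyl = 0, phosphoryl = 0, amine = 0,
                                    hydroxyl = 0, unassigned = 0)))
  rep2 <- render_table1_report(list(A = s, B = s0), input_units = "mmol_per_g")
  expect_equal(ncol(rep2), 4)
  expect_match(rep2[["B Average L_T (mMol/g EPS)"]][1], "0\\.000 ± NA")
  # mol/g inputs are converted to mMol/g for display
  rep3 <- render_table1_report(list(A = s))
  expect_match(rep3[[3]][1], "^113\\.000")
})
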