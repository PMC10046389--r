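# calreticulin C-domain sequence features

wt <- calr_c_domain()$sequence

test_that("stop and substitution variants edit the fragment correctly", {
  d_seq <- apply_simple_variant(wt, "p.E389*")
  expect_equal(nchar(d_seq), 37L)              # 388 - 352 + 1
  expect_identical(d_seq, substr(wt, 1, 37))

  e_seq <- apply_simple_variant(wt, "p.L367I")
  expect_equal(nchar(e_seq), nchar(wt))
  expect_identical(substr(e_seq, 16, 16), "I")  # author 367
  expect_identical(substr(wt, 16, 16), "L")

  expect_error(apply_simple_variant(wt, "p.A352*"), "empty fragment")
  expect_error(apply_simple_variant(wt, "p.E9999D"), "outside the fragment")
  expect_error(apply_simple_variant(wt, "p.K367I"), "mismatch")
  expect_error(apply_simple_variant(wt, "p.L367Tfs*46"), "frameshift")
})

test_that("net formal charge counts K/R against D/E", {
  expect_equal(net_formal_charge("DE"), -2L)
  expect_equal(net_formal_charge("KRDE"), 0L)
  expect_equal(net_formal_charge("HHH"), 0L)
  expect_equal(net_formal_charge(wt), -26L)
  expect_equal(net_formal_charge(apply_simple_variant(wt, "p.E389*")), -9L)
})

test_that("counter-ion requirements follow charge and valence", {
  expect_equal(counterion_requirement(-26, "Ca2+"), 13L)
  expect_equal(counterion_requirement(-26, "Na+"), 26L)
  expect_equal(counterion_requirement(15, "Cl-"), 15L)
  expect_equal(counterion_requirement(15, "Ca2+"), 0L)   # wrong sign
  expect_equal(counterion_requirement(0, "Na+"), 0L)
  # property: monovalent needs |q|, divalent ceil(|q| / 2)
  for (q in -30:30) {
    if (q < 0) {
      expect_equal(counterion_requirement(q, "Na+"), abs(q))
      expect_equal(counterion_requirement(q, "Ca2+"),
                   as.integer(ceiling(abs(q) / 2)))
    } else if (q > 0) {
      expect_equal(counterion_requirement(q, "Cl-"), q)
    }
  }
})

test_that("KDEL must be the terminal tetrapeptide", {
  expect_true(detect_kdel(wt))
  expect_false(detect_kdel(apply_simple_variant(wt, "p.E389*")))
  expect_false(detect_kdel(paste0(wt, "X")))   # "KDELX" suffix
  expect_true(detect_kdel(apply_simple_variant(wt, "p.L367I")))
})

test_that("cysteine counting and CREAC motif detection", {
  expect_equal(detect_creac_cysteines("AAACREAC"),
               list(n_cys = 2L, has_creac = TRUE))
  expect_equal(detect_creac_cysteines(wt), list(n_cys = 0L, has_creac = FALSE))
  expect_equal(detect_creac_cysteines("CAAAAAAAAAAAAAAA"),
               list(n_cys = 1L, has_creac = FALSE))
  # motif outside the terminal window is not a dimerization motif
  expect_false(detect_creac_cysteines(
    paste0("AAACREAC", strrep("G", 20)))$has_creac)
})

test_that("helix percentage follows the inclusive interval arithmetic", {
  expect_equal(helix_fraction(list(c(366, 388)), 60), 38L)  # class A
  expect_equal(helix_fraction(NULL, 60), 0L)
  expect_equal(helix_fraction(list(c(352, 411)), 60), 100L)
  expect_error(helix_fraction(list(c(352, 370), c(365, 380)), 60),
               "overlapping")
})

test_that("the feature table reproduces the published sequence-level values", {
  ft <- build_feature_table(calr_variants(), calr_helix_annotations())
  row <- function(id) ft[ft$system == id, ]

  expect_equal(row("CALRwt")$length, 66L)
  expect_true(row("CALRwt")$kdel)
  expect_equal(row("CALRwt")$charge, -26L)
  expect_equal(row("CALRwt")$n_cys, 0L)
  expect_equal(row("CALRwt")$counterion, "Ca2+")
  expect_equal(row("CALRwt")$counterion_n, 13L)
  expect_false(row("CALRwt")$dimer_capable)

  expect_equal(row("CALRm_A")$length, 60L)
  expect_false(row("CALRm_A")$kdel)
  expect_equal(row("CALRm_A")$charge, 15L)
  expect_equal(row("CALRm_A")$helix_percent, 38L)
  expect_true(row("CALRm_A")$has_creac)
  expect_true(row("CALRm_A")$dimer_capable)
  expect_equal(row("CALRm_A")$counterion, "Cl-")
  expect_equal(row("CALRm_A")$counterion_n, 15L)

  expect_equal(row("CALRm_B")$length, 79L)
  expect_equal(row("CALRm_B")$charge, 9L)
  expect_true(row("CALRm_B")$dimer_capable)

  expect_equal(row("CALRm_C")$length, 78L)
  expect_equal(row("CALRm_C")$charge, 15L)

  expect_equal(row("CALRm_D")$length, 37L)
  expect_false(row("CALRm_D")$kdel)
  expect_equal(row("CALRm_D")$charge, -9L)
  expect_false(row("CALRm_D")$dimer_capable)

  expect_equal(row("CALRm_E")$length, 66L)
  expect_true(row("CALRm_E")$kdel)
  expect_equal(row("CALRm_E")$charge, -26L)
  expect_false(row("CALRm_E")$dimer_capable)
})

test_that("fragment FASTA reading honours start annotations", {
  path <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">frag1 start=100", "KDEL", ">frag2", "AAAA"), path)
  fx <- read_fragment_fasta(path)
  expect_equal(fx$frag1$start, 100L)
  expect_equal(fx$frag2$start, 352L)
  expect_equal(fx$frag1$sequence, "KDEL")
})
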