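test_that("designEra returns the reverse complement over the paired span", {
  cr <- crrna22()
  era <- designEra(cr, "5prime", 7)
  expect_identical(era@pairedSpan, c(8L, 22L))
  expect_identical(as.character(era@sequence),
                   as.character(Biostrings::reverseComplement(
                     Biostrings::RNAString(substr(SPACER22, 8, 22)))))

  ## a declared mismatch changes exactly one base
  eraMm <- designEra(cr, "5prime", 7, eraMismatches = 9)
  a <- strsplit(as.character(era@sequence), "")[[1]]
  b <- strsplit(as.character(eraMm@sequence), "")[[1]]
  expect_equal(sum(a != b), 1)
  lay <- buildDuplexLayout(cr, eraMm, designActivator(cr))
  expect_identical(lay@eraMismatchDistances, 1L)
})

test_that("designEra rejects degenerate and ill-placed requests", {
  cr <- crrna22()
  expect_error(designEra(cr, "5prime", 22), "empty duplex")
  expect_error(designEra(cr, "5prime", 7, eraMismatches = 3),
               "mismatch outside duplex")
})

test_that("buildDuplexLayout derives direction, toeholds and bm length", {
  cr <- crrna22()
  act <- designActivator(cr)
  lay5 <- buildDuplexLayout(cr, ERASpec(designEra(cr, "5prime", 7)@sequence,
                                        c(8, 22)), act)
  expect_identical(toeholdDirection(lay5), "5prime")
  expect_identical(toeholdLengthF(lay5), 7L)
  expect_identical(toeholdLengthR(lay5), 0L)
  expect_identical(bmLength(lay5), 15L)

  lay3 <- buildDuplexLayout(cr, designEra(cr, "3prime", 7), act)
  expect_identical(toeholdDirection(lay3), "3prime")
  expect_identical(toeholdLengthF(lay3), 7L)
  expect_identical(bmLength(lay3), 15L)

  ## toehold-exchange case: 5-nt forward toehold, 5-nt terminal deletion on
  ## the opposite end becomes the reverse toehold
  layTe <- buildDuplexLayout(cr, designEra(cr, "5prime", 5),
                             designActivator(cr, deletion3p = 5))
  expect_identical(toeholdLengthF(layTe), 5L)
  expect_identical(toeholdLengthR(layTe), 5L)
})

test_that("buildDuplexLayout rejects inconsistent inputs", {
  cr <- crrna22()
  act <- designActivator(cr)
  ## unpaired on both ends
  midEra <- ERASpec(as.character(Biostrings::reverseComplement(
    Biostrings::RNAString(substr(SPACER22, 5, 18)))), c(5, 18))
  expect_error(buildDuplexLayout(cr, midEra, act), "ambiguous layout")
  ## sequence does not match the declared span / mismatch set
  bad <- ERASpec(paste(rep("A", 15), collapse = ""), c(8, 22))
  expect_error(buildDuplexLayout(cr, bad, act), "sequence/span inconsistency")
  ## undeclared activator mismatch
  actBad <- ActivatorSpec(chartr("GT", "TG", as.character(
    designActivator(cr)@sequence)))
  expect_error(buildDuplexLayout(cr, designEra(cr, "5prime", 7), actBad),
               "sequence/span inconsistency")
})

test_that("layout round-trips the designer over both directions and all toeholds", {
  cr <- crrna22()
  act <- designActivator(cr)
  L <- spacerLength(cr)
  for (dirn in c("5prime", "3prime")) {
    for (f in 1:(L - 1)) {
      lay <- buildDuplexLayout(cr, designEra(cr, dirn, f), act)
      expect_identical(toeholdDirection(lay), dirn)
      expect_identical(toeholdLengthF(lay), f)
      expect_identical(bmLength(lay), L - f)
      expect_identical(toeholdLengthR(lay), 0L)
    }
  }
  ## f = 0 degenerate: full-span ERA, no toehold to recover
  lay0 <- buildDuplexLayout(cr, designEra(cr, "5prime", 0), act)
  expect_identical(toeholdLengthF(lay0), 0L)
  expect_identical(bmLength(lay0), L)
})

test_that("designer output is deterministic", {
  cr <- crrna22()
  e1 <- designEra(cr, "3prime", 6, eraMismatches = 4)
  e2 <- designEra(cr, "3prime", 6, eraMismatches = 4)
  expect_identical(as.character(e1@sequence), as.character(e2@sequence))
})

test_that("mismatchDistance measures from the toehold-proximal bm boundary", {
  lay5 <- layoutF(7, "5prime")
  expect_identical(mismatchDistance(lay5, 8), 0L)
  expect_identical(mismatchDistance(lay5, 22), 14L)
  expect_error(mismatchDistance(lay5, 4), "position in toehold")
  ## direction mirror: same offset within the bm domain maps d -> bm-1-d
  lay3 <- layoutF(7, "3prime")
  bm <- bmLength(lay5)
  for (off in c(0L, 3L, 9L, bm - 1L)) {
    d5 <- mismatchDistance(lay5, lay5@bmStart + off)
    d3 <- mismatchDistance(lay3, lay3@bmStart + off)
    expect_identical(d3, bm - 1L - d5)
  }
  expect_error(mismatchDistance(lay3, 20), "position in toehold")
})

test_that("toehold-exchange designer enforces the feasibility bounds", {
  cr <- crrna22()
  te <- designTeEra(cr, "3prime", fLength = 9, rLength = 4)
  lay <- buildDuplexLayout(cr, te$era, te$activator)
  expect_identical(toeholdLengthF(lay), 9L)
  expect_identical(toeholdLengthR(lay), 4L)
  expect_error(designTeEra(cr, "3prime", 9, 5), "reverse toehold infeasible")
  expect_error(designTeEra(cr, "5prime", 5, 5), "reverse toehold infeasible")

  cr35 <- crrna35()
  te35 <- designTeEra(cr35, "5prime", 7, 19)
  lay35 <- buildDuplexLayout(cr35, te35$era, te35$activator)
  expect_identical(toeholdLengthR(lay35), 19L)
  expect_error(designTeEra(cr35, "5prime", 7, 20), "reverse toehold infeasible")
})

test_that("mismatch substitutions never pair with the spacer", {
  cr <- crrna22()
  comp <- c(A = "U", C = "G", G = "C", U = "A")
  for (pos in c(9, 12, 15, 20)) {
    era <- designEra(cr, "5prime", 7, eraMismatches = pos)
    spc <- strsplit(SPACER22, "")[[1]]
    j <- era@pairedSpan[2] - pos + 1  # antiparallel index
    base <- strsplit(as.character(era@sequence), "")[[1]][j]
    expect_false(base == comp[spc[pos]])
    ## no wobble either
    expect_false(paste0(spc[pos], base) %in% c("GU", "UG"))
  }
})
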