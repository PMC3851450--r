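test_that("aac computes order-free residue frequencies that sum to 1", {
  expect_equal(unname(aac("AAAA")["A"]), 1)
  expect_equal(unname(aac("ACDE")[c("A", "C", "D", "E")]), rep(0.25, 4))
  expect_length(aac("ACDE"), 20L)
  set.seed(11)
  for (i in 1:10) {
    s <- random_seq(sample(5:150, 1))
    shuffled <- paste(sample(strsplit(s, "")[[1]]), collapse = "")
    expect_equal(aac(s), aac(shuffled))
    expect_equal(sum(aac(s)), 1, tolerance = 1e-9)
  }
  expect_error(aac(""), class = "plastidclass_data_error")
})

test_that("dipep computes the 400 ordered adjacent-pair frequencies", {
  d <- dipep("AAA")
  expect_length(d, 400L)
  expect_equal(unname(d["A.A"]), 1)
  d2 <- dipep("ACA")
  expect_equal(unname(d2[c("A.C", "C.A")]), c(0.5, 0.5))
  set.seed(12)
  for (i in 1:5) expect_equal(sum(dipep(random_seq(80))), 1, tolerance = 1e-9)
  expect_error(dipep("A"), class = "plastidclass_data_error")
})

test_that("pseaac matches the naive double-loop oracle and the stated structure", {
  ## homopolymer: every tier-tau factor is the squared standardized value
  p <- pseaac_params()
  s <- strrep("A", 10)
  v <- pseaac(s, p)
  expect_length(v, 30L)
  hA <- p$h1[["A"]]; gA <- p$h2[["A"]]
  theta_exp <- rep(c(hA^2, gA^2), 5)
  D <- 1 + 0.1 * sum(theta_exp)
  expect_equal(unname(v[21:30]), 0.1 * theta_exp / D, tolerance = 1e-12)
  expect_equal(as.numeric(v), naive_pseaac(s), tolerance = 1e-10)

  ## first-20 block proportional to aac, single ratio
  set.seed(13)
  s2 <- random_seq(60)
  v2 <- pseaac(s2, p)
  a2 <- aac(s2)
  ratio <- v2[1:20][a2 > 0] / a2[a2 > 0]
  expect_lt(diff(range(ratio)), 1e-12)

  ## oracle equivalence on random sequences
  for (i in 1:20) {
    s3 <- random_seq(sample(10:200, 1))
    v3 <- pseaac(s3, p)
    expect_equal(as.numeric(v3), naive_pseaac(s3), tolerance = 1e-10)
  }
  ## custom lambda changes arity; precondition L > lambda enforced
  expect_length(pseaac(random_seq(30), pseaac_params(lam = 8)), 36L)
  expect_error(pseaac("ACDEF", pseaac_params(lam = 5)), "lambda",
               class = "plastidclass_data_error")
})

test_that("standardized scales have mean 0 and unit variance over 20 residues", {
  for (sc in list(TANFORD_HYDROPHOBICITY, HOPP_WOODS_HYDROPHILICITY)) {
    z <- standardize_scale(sc)
    expect_equal(mean(z), 0, tolerance = 1e-9)
    expect_equal(sum(z^2) / 20, 1, tolerance = 1e-9)
  }
})

test_that("ncc concatenates N/Center/C compositions with the short-sequence thirds rule", {
  v <- ncc(paste0(strrep("A", 25), strrep("C", 25), strrep("D", 25)))
  expect_length(v, 60L)
  expect_equal(unname(v[c("N.A", "Center.C", "C.D")]), c(1, 1, 1))
  ## short sequence: thirds of 3
  v2 <- ncc("AAACCCDDD", terminal_len = 25)
  expect_equal(unname(v2[c("N.A", "Center.C", "C.D")]), c(1, 1, 1))
  ## each 20-block sums to 1
  set.seed(14)
  for (i in 1:5) {
    v3 <- ncc(random_seq(sample(c(10, 51, 300), 1)))
    expect_equal(unname(vapply(c(0, 20, 40), function(o) sum(v3[o + 1:20]),
                               numeric(1))), rep(1, 3), tolerance = 1e-9)
  }
  ## NOT permutation invariant: moving residues across segment boundaries
  a <- paste0(strrep("A", 30), strrep("C", 30))
  b <- paste0(strrep("C", 30), strrep("A", 30))
  expect_false(isTRUE(all.equal(ncc(a), ncc(b))))
  expect_error(ncc("AC"), class = "plastidclass_data_error")
})

test_that("physchem features equal aac sums over each class, pI scaled by 14", {
  tab <- property_class_table()
  expect_length(tab, 20L)
  expect_equal(tab$Cyclic, "P")
  expect_equal(tab$Covalent.crosslink, "C")
  expect_length(tab$Hydrophobic.neutral, 10L)

  p <- physchem("P")
  expect_equal(unname(p[c("Cyclic", "Tiny", "Hydrophobic.neutral", "Charged")]),
               c(1, 1, 1, 0))
  pc <- physchem("C")
  expect_equal(unname(pc[c("Sulfur.containing", "Covalent.crosslink",
                           "Ionizable", "H.bonding")]), c(1, 1, 1, 1))
  expect_equal(unname(physchem("DR")["Charged"]), 1)

  set.seed(15)
  s <- random_seq(120)
  v <- physchem(s); a <- aac(s)
  for (k in setdiff(names(tab), "Theoretical.pI"))
    expect_equal(unname(v[k]), sum(a[tab[[k]]]), tolerance = 1e-12)
  expect_equal(unname(v["Theoretical.pI"]), theoretical_pi(s) / 14,
               tolerance = 1e-9)
})

test_that("theoretical pI zeroes the net charge and orders basic/acidic polymers", {
  ## independent check: recompute the net charge at the reported pI
  charge_at <- function(s, ph) {
    ch <- strsplit(s, "")[[1]]
    pka <- list(C = 8.5, D = 3.9, E = 4.1, Y = 10.1, H = 6.5, K = 10.8, R = 12.5)
    pos <- 1 / (1 + 10^(ph - 8.6)) +
      sum(vapply(c("H", "K", "R"), function(r)
        sum(ch == r) / (1 + 10^(ph - pka[[r]])), numeric(1)))
    neg <- 1 / (1 + 10^(3.6 - ph)) +
      sum(vapply(c("C", "D", "E", "Y"), function(r)
        sum(ch == r) / (1 + 10^(pka[[r]] - ph)), numeric(1)))
    pos - neg
  }
  set.seed(16)
  for (s in c(strrep("K", 10), strrep("D", 10), random_seq(80), "G")) {
    pi_val <- theoretical_pi(s)
    expect_lt(abs(charge_at(s, pi_val)), 1e-2)
  }
  expect_gt(theoretical_pi(strrep("K", 10)), 9)
  expect_lt(theoretical_pi(strrep("D", 10)), 4.5)
})

test_that("extract builds row-ordered matrices and reports exclusions", {
  set.seed(17)
  r <- random_records(3)
  m <- extract(r, "AAC")
  expect_equal(dim(m), c(3L, 20L))
  expect_equal(rownames(m), r$id)

  r2 <- protein_records(c("long", "tiny"), c(random_seq(50), "A"))
  m2 <- extract(r2, "DIPEP")
  expect_equal(rownames(m2), "long")
  expect_equal(attr(m2, "excluded")$id, "tiny")

  m0 <- extract(r[0, ], "AAC")
  expect_equal(dim(m0), c(0L, 20L))
  expect_equal(colnames(m0), AA_ALPHABET20)
  expect_error(extract(r, "BOGUS"), class = "plastidclass_usage_error")
})

test_that("feature matrices round-trip through TSV", {
  set.seed(18)
  m <- extract(random_records(4), "PHYSCHEM")
  f <- withr::local_tempfile(fileext = ".tsv")
  write_features(m, f)
  back <- read_features(f)
  expect_equal(as.vector(back), as.vector(m), tolerance = 1e-12)
  expect_equal(attr(back, "scheme"), "PHYSCHEM")
  expect_equal(rownames(back), rownames(m))
})

test_that("compare_compositions finds a planted single-residue shift", {
  set.seed(19)
  same <- random_records(5, prefix = "a")
  cc0 <- compare_compositions(same, same)
  expect_equal(nrow(cc0), 20L)
  expect_equal(cc0$diff, rep(0, 20))

  ## profiles differing only in S
  f1 <- rep(1 / 20, 20)
  f2 <- f1; f2[match("S", AA20)] <- f2[match("S", AA20)] * 2
  f2 <- f2 / sum(f2)
  a <- random_records(200, c(150, 250), freq = f1, prefix = "p")
  b <- random_records(200, c(150, 250), freq = f2, prefix = "q")
  cc <- compare_compositions(a, b)
  expect_equal(cc$residue[which.min(cc$p)], "S")
})
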