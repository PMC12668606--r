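# interface detection, pLDDT_binder, PAE_interaction, CUTRE

two_chain_bundle <- function(nb, nt, pae_fill, plddt_fill) {
  n <- nb + nt
  confidence_bundle(rep(plddt_fill, n),
                    matrix(pae_fill, n, n),
                    list(A = 1:nb, B = nb + 1:nt))
}

test_that("bundle invariants are enforced", {
  expect_error(confidence_bundle(c(50, 50), matrix(1, 3, 3),
                                 list(A = 1:2, B = 3)), "square")
  expect_error(confidence_bundle(c(50, 150), matrix(1, 2, 2),
                                 list(A = 1, B = 2)), "0, 100")
  expect_error(confidence_bundle(c(50, 50), matrix(-1, 2, 2),
                                 list(A = 1, B = 2)), ">= 0")
  expect_error(confidence_bundle(c(50, 50), matrix(1, 2, 2),
                                 list(A = 1, B = 3)), "partition")
})

test_that("interface boundary is inclusive at the cutoff", {
  mk <- function(gap) {
    make_complex(build_ideal_backbone(list(c("coil", 2))),
                 build_ideal_backbone(list(c("coil", 2)), "B"),
                 min_gap = gap, seed = 5)
  }
  # placement tolerance is 0.1 A, so probe clearly inside/outside
  near <- interface_residues(mk(9.5))
  expect_gt(length(near$binder_residues), 0)
  expect_gt(length(near$target_residues), 0)
  far <- interface_residues(mk(10.5))
  expect_equal(length(far$binder_residues), 0)
  expect_equal(length(far$target_residues), 0)
  # exact boundary: construct atoms precisely 10.0 A apart
  at <- build_ideal_backbone(list(c("coil", 1)))[1:2, ]
  bt <- at; bt$chain <- "B"; bt$x <- bt$x + 10.0 + (at$x[2] - at$x[1])
  m <- binderscreen:::new_complex_model(rbind(at, bt), "A", "B")
  ii <- interface_residues(m, cutoff = 10.0)
  expect_equal(length(ii$binder_residues), 1L)
  expect_equal(length(ii$target_residues), 1L)
})

test_that("interface sets are nested as the cutoff grows", {
  m <- fixture_bundle_complex(min_gap = 4, seed = 6)
  i6 <- interface_residues(m, 6)
  i10 <- interface_residues(m, 10)
  i14 <- interface_residues(m, 14)
  expect_true(all(i6$binder_residues %in% i10$binder_residues))
  expect_true(all(i10$binder_residues %in% i14$binder_residues))
  expect_true(all(i6$target_residues %in% i10$target_residues))
  expect_true(all(i10$target_residues %in% i14$target_residues))
})

test_that("plddt_binder is the arithmetic mean over the binder span", {
  b <- two_chain_bundle(2, 3, 1, 80)
  expect_equal(plddt_binder(b), 80)
  b2 <- confidence_bundle(c(70, 90, 50, 50, 50), matrix(1, 5, 5),
                          list(A = 1:2, B = 3:5))
  expect_equal(plddt_binder(b2), 80)
  set.seed(9)
  v <- runif(12, 0, 100)
  b3 <- confidence_bundle(v, matrix(1, 12, 12), list(A = 1:7, B = 8:12))
  expect_equal(plddt_binder(b3), mean(v[1:7]))
})

test_that("pae_interaction is the symmetric two-block mean", {
  expect_equal(pae_interaction(two_chain_bundle(3, 4, 5, 90)), 5)
  # binder->target block 4, target->binder block 8 -> 6
  pae <- matrix(0, 5, 5)
  pae[1:2, 3:5] <- 4; pae[3:5, 1:2] <- 8
  b <- confidence_bundle(rep(90, 5), pae, list(A = 1:2, B = 3:5))
  expect_equal(pae_interaction(b), 6)
  # minimal 1+1 complex
  b2 <- confidence_bundle(c(90, 90), matrix(c(0, 7, 3, 0), 2, 2),
                          list(A = 1, B = 2))
  expect_equal(pae_interaction(b2), 5)
})

test_that("pae_interaction is invariant under consistent within-chain permutation", {
  set.seed(10)
  pae <- matrix(runif(64, 0, 30), 8, 8)
  b <- confidence_bundle(rep(90, 8), pae, list(A = 1:3, B = 4:8))
  perm <- c(sample(1:3), 3 + sample(1:5))
  b2 <- confidence_bundle(rep(90, 8), pae[perm, perm], list(A = 1:3, B = 4:8))
  expect_equal(pae_interaction(b2), pae_interaction(b), tolerance = 1e-12)
})

test_that("CUTRE closed forms hold for constant blocks", {
  iface <- structure(list(target_residues = 4:6, binder_residues = 1:2,
                          cutoff = 10), class = "interface_set")
  expect_equal(cutre(two_chain_bundle(3, 3, 10, 100), iface), 10)
  expect_equal(cutre(two_chain_bundle(3, 3, 10, 50), iface), 5)
})

test_that("CUTRE equals the naive quadruple-loop oracle on random instances", {
  set.seed(11)
  for (k in 1:50) {
    nb <- sample(2:10, 1); nt <- sample(2:10, 1)
    n <- nb + nt
    pae <- matrix(runif(n * n, 0, 30), n, n)
    plddt <- runif(n, 20, 100)
    b <- confidence_bundle(plddt, pae, list(A = 1:nb, B = nb + 1:nt))
    B_set <- sort(sample(1:nb, sample(1:nb, 1)))
    T_set <- sort(sample(nb + 1:nt, sample(1:nt, 1)))
    iface <- structure(list(target_residues = T_set, binder_residues = B_set,
                            cutoff = 10), class = "interface_set")
    expect_equal(cutre(b, iface), naive_cutre(pae, plddt, T_set, B_set),
                 tolerance = 1e-12)
  }
})

test_that("CUTRE is linear in PAE, bounded by max(PAE), and reduces to plain mean at pLDDT 100", {
  set.seed(12)
  n <- 10
  pae <- matrix(runif(n * n, 0, 30), n, n)
  plddt <- runif(n, 10, 100)
  spans <- list(A = 1:4, B = 5:10)
  iface <- structure(list(target_residues = 5:8, binder_residues = 1:3,
                          cutoff = 10), class = "interface_set")
  b1 <- confidence_bundle(plddt, pae, spans)
  b2 <- confidence_bundle(plddt, 2.5 * pae, spans)
  expect_equal(cutre(b2, iface), 2.5 * cutre(b1, iface), tolerance = 1e-12)
  expect_lte(cutre(b1, iface), max(pae))
  expect_gte(cutre(b1, iface), 0)
  b3 <- confidence_bundle(rep(100, n), pae, spans)
  plain <- (mean(pae[5:8, 1:3]) + mean(pae[1:3, 5:8])) / 2
  expect_equal(cutre(b3, iface), plain, tolerance = 1e-12)
})

test_that("an empty interface is an error, not a score", {
  b <- two_chain_bundle(2, 2, 5, 90)
  iface <- structure(list(target_residues = integer(0),
                          binder_residues = integer(0), cutoff = 10),
                     class = "interface_set")
  expect_error(cutre(b, iface), "empty interface")
})

test_that("AF2-style JSON round-trips into a bundle", {
  n <- 6
  pae <- matrix(runif(n * n, 0, 20), n, n)
  plddt <- runif(n, 50, 100)
  f <- tempfile(fileext = ".json")
  jsonlite::write_json(list(predicted_aligned_error = pae, plddt = plddt),
                       f, digits = NA, matrix = "rowmajor")
  b <- read_af2_json(f, list(A = 1:2, B = 3:6))
  expect_equal(b$pae, pae, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(b$plddt, plddt, tolerance = 1e-12)
  expect_error(read_af2_json(f, list(A = 1:2, B = 3:5)), "partition")
})

test_that("pLDDT can be lifted from the B-factor column per residue", {
  m <- fixture_bundle_complex()
  v <- seq_len(n_residues(m, "A") + n_residues(m, "B")) + 0.5
  spans <- model_chain_spans(m)
  for (ch in names(spans)) {
    sel <- m$atoms$chain == ch
    key <- paste(m$atoms$resno[sel], m$atoms$ins[sel], sep = "|")
    m$atoms$b[sel] <- v[spans[[ch]][match(key, unique(key))]]
  }
  expect_equal(plddt_from_bfactor(m), v)
})
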