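# secondary-structure assignment, topology classification, clash filter,
# template grafting

test_that("an ideal alpha-helix assigns mostly H and no E", {
  m <- fixture_helix_model(30)
  ss <- assign_secondary_structure(m, "A")
  sym <- strsplit(ss, "")[[1]]
  expect_gte(mean(sym == "H"), 0.8)
  expect_false(any(sym == "E"))
})

test_that("an antiparallel strand pair assigns E in the strand cores", {
  at <- build_antiparallel_pair(6)
  m <- binderscreen:::new_complex_model(at, "A", character(0))
  ss <- assign_secondary_structure(m, "A")
  sym <- strsplit(ss, "")[[1]]
  expect_gte(sum(sym[1:6] == "E"), 2)
  expect_gte(sum(sym[7:12] == "E"), 2)
  expect_false(any(sym == "H"))
})

test_that("chains too short for any element are all coil", {
  m <- fixture_helix_model(3)
  expect_equal(assign_secondary_structure(m, "A"), "CCC")
})

test_that("missing backbone atoms are reported by residue", {
  at <- build_ideal_backbone(list(c("helix", 6)))
  at <- at[!(at$resno == 4 & at$atom == "O"), ]
  m <- binderscreen:::new_complex_model(at, "A", character(0))
  expect_error(assign_secondary_structure(m, "A"), "4.*O|O.*4")
})

test_that("segmentize keeps maximal runs above the length minima", {
  segs <- segmentize("CCHHHHHHCC")
  expect_equal(nrow(segs), 1L)
  expect_equal(segs$type, "helix")
  expect_equal(c(segs$start, segs$end), c(2L, 7L))
  expect_equal(nrow(segmentize("HHH", min_len_h = 4)), 0L)
  ss <- "HHHHHCCEEECHHH"
  segs <- segmentize(ss)
  retained <- sum(segs$end - segs$start + 1L)
  expect_equal(retained, 5L + 3L)   # the 3-residue trailing H run is dropped
  expect_error(segmentize("HXZ"), "symbols")
})

test_that("topology classification rejects long single helices and hairpins only", {
  long_h <- classify_topology(strrep("H", 80))
  expect_equal(long_h$klass, "single_helix")
  expect_true(long_h$rejected)

  short_h <- classify_topology(strrep("H", 30))
  expect_equal(short_h$klass, "other")
  expect_false(short_h$rejected)

  hp <- classify_topology("CEEEEECCEEEEEC")
  expect_equal(hp$klass, "hairpin")
  expect_true(hp$rejected)

  bundle <- classify_topology("HHHHHCCCHHHHHCCCHHHHH")
  expect_equal(bundle$klass, "other")
  expect_false(bundle$rejected)

  # mixed alpha/beta with two strands is retained (not an isolated hairpin)
  mixed <- classify_topology("HHHHHCEEECCEEEC")
  expect_equal(mixed$klass, "other")
})

test_that("topology depends only on the ss string, not coordinates", {
  m <- fixture_helix_model(45)
  ss <- assign_secondary_structure(m, "A")
  v1 <- classify_topology(ss)
  rot <- m
  R <- random_rotation()
  rot$atoms[, c("x", "y", "z")] <-
    as.matrix(rot$atoms[, c("x", "y", "z")]) %*% t(R)
  v2 <- classify_topology(assign_secondary_structure(rot, "A"))
  expect_identical(v1$klass, v2$klass)
})

test_that("clash filter applies the strict 0.5 A rule", {
  fails <- make_complex(build_ideal_backbone(list(c("helix", 10))),
                        build_ideal_backbone(list(c("helix", 10)), "B"),
                        min_gap = 0.4, seed = 2)
  res <- clash_filter(fails, cutoff = 0.5)
  expect_false(res$passes)
  expect_gte(res$n_clashes, 1L)

  passes <- make_complex(build_ideal_backbone(list(c("helix", 10))),
                         build_ideal_backbone(list(c("helix", 10)), "B"),
                         min_gap = 0.6, seed = 2)
  expect_true(clash_filter(passes, cutoff = 0.5)$passes)
})

test_that("clash counts equal the exhaustive oracle and are monotone in cutoff", {
  set.seed(7)
  nb <- 60
  at <- fixture_bundle_complex(min_gap = 1, seed = 3)
  bx <- as.matrix(chain_atoms(at, "A")[, c("x", "y", "z")])
  tx <- as.matrix(chain_atoms(at, "B")[, c("x", "y", "z")])
  for (cut in c(1, 2, 4)) {
    d <- sqrt(outer(rowSums(bx^2), rowSums(tx^2), "+") - 2 * bx %*% t(tx))
    expect_equal(clash_filter(at, cut)$n_clashes, sum(d < cut))
  }
  n1 <- clash_filter(at, 1)$n_clashes
  n2 <- clash_filter(at, 3)$n_clashes
  expect_lte(n1, n2)
})

test_that("grafting an identical template reproduces the cropped target", {
  m <- fixture_bundle_complex()
  tpl <- binderscreen:::subset_chains(m, "B")
  tpl$binder_chain <- "B"; tpl$target_chains <- character(0)
  out <- graft_template(m, tpl, "B")
  expect_lt(attr(out, "graft_rmsd"), 1e-9)
  expect_equal(as.matrix(out$atoms[, c("x", "y", "z")]),
               as.matrix(m$atoms[, c("x", "y", "z")]), tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("grafting a transformed extended template recovers it and leaves the binder untouched", {
  m <- fixture_bundle_complex()
  # full template: cropped span plus 20 flanking residues, rigidly moved
  full <- build_ideal_backbone(list(c("helix", 35)), chain_id = "T")
  # design target = template residues 11..25 by construction
  tgt <- chain_atoms(m, "B")
  sp <- kabsch_superpose(
    as.matrix(full[full$atom == "CA" & full$resno %in% 11:25,
                   c("x", "y", "z")]),
    as.matrix(tgt[tgt$atom == "CA", c("x", "y", "z")]))
  full[, c("x", "y", "z")] <- apply_superposition(sp, as.matrix(
    full[, c("x", "y", "z")]))
  full$resno <- full$resno - 10L          # template numbering 1..35 -> -9..25
  set.seed(8)
  R <- random_rotation(); tv <- rnorm(3, sd = 10)
  full[, c("x", "y", "z")] <-
    as.matrix(full[, c("x", "y", "z")]) %*% t(R) +
    matrix(tv, nrow(full), 3, byrow = TRUE)
  tpl <- binderscreen:::new_complex_model(full, "T", character(0))

  before <- chain_atoms(m, "A")
  out <- graft_template(m, tpl, "T")
  expect_lt(attr(out, "graft_rmsd"), 1e-6)
  expect_equal(attr(out, "n_shared_ca"), 15L)
  expect_identical(chain_atoms(out, "A"), before)   # bit-exact binder
  expect_equal(n_residues(out, "B"), 35L)

  # disjoint numbering -> graft error
  tpl2 <- tpl
  tpl2$atoms$resno <- tpl2$atoms$resno + 1000L
  expect_error(graft_template(m, tpl2, "T"), "shared CA")
})

test_that("backbone_filter rejects clashes before topology and reports reasons", {
  clashing <- fixture_bundle_complex(min_gap = 0.2, seed = 4)
  fl <- backbone_filter(clashing)
  expect_false(fl$passes)
  expect_match(fl$reason, "steric_clash")

  helix_binder <- make_complex(build_ideal_backbone(list(c("helix", 45))),
                               build_ideal_backbone(list(c("helix", 10)), "B"),
                               min_gap = 5, seed = 4)
  fl2 <- backbone_filter(helix_binder)
  expect_false(fl2$passes)
  expect_equal(fl2$reason, "single_helix")

  ok <- fixture_bundle_complex(min_gap = 5, seed = 4)
  expect_true(backbone_filter(ok)$passes)
})
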