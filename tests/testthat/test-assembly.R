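# Superposition, clash screening, interface-gap classification, assembly
# and the retention filter.

test_that("superpose recovers known rigid transforms", {
  set.seed(1)
  A <- matrix(rnorm(30, sd = 5), ncol = 3)
  # identity
  tr <- superpose(A, A)
  expect_equal(tr$rotation, diag(3), tolerance = 1e-12)
  expect_lt(tr$rmsd, 1e-12)
  # known rotation + translation recovered to numerical precision
  R <- random_rotation(); tvec <- c(3, -2, 7)
  B <- sweep(A %*% t(R), 2, tvec, "+")
  tr2 <- superpose(A, B)
  expect_equal(tr2$rotation, R, tolerance = 1e-9)
  expect_equal(tr2$translation, tvec, tolerance = 1e-9)
  expect_lt(tr2$rmsd, 1e-9)
  # never a reflection
  expect_equal(det(tr2$rotation), 1, tolerance = 1e-9)
  # degenerate input errors
  expect_error(superpose(A[1:2, ], A[1:2, ]), "at least 3")
  L <- cbind(1:5, 2 * (1:5), 3 * (1:5))
  expect_error(superpose(L, L), "collinear")
})

test_that("superpose matches the quaternion oracle on noisy instances", {
  set.seed(99)
  for (i in 1:25) {
    A <- matrix(rnorm(36, sd = 4), ncol = 3)
    B <- sweep(A %*% t(random_rotation()), 2, rnorm(3, sd = 5), "+") +
      matrix(rnorm(36, sd = 0.3), ncol = 3)
    tr <- superpose(A, B)
    qo <- quaternion_superpose(A, B)
    expect_equal(tr$rmsd, qo$rmsd, tolerance = 1e-9)
    expect_equal(tr$rotation, qo$rotation, tolerance = 1e-6)
  }
})

test_that("superpose RMSD is invariant under a common rigid motion", {
  set.seed(3)
  A <- matrix(rnorm(30, sd = 5), ncol = 3)
  B <- A + matrix(rnorm(30, sd = 0.5), ncol = 3)
  base <- superpose(A, B)$rmsd
  R <- random_rotation(); tvec <- rnorm(3, sd = 10)
  A2 <- sweep(A %*% t(R), 2, tvec, "+")
  B2 <- sweep(B %*% t(R), 2, tvec, "+")
  expect_equal(superpose(A2, B2)$rmsd, base, tolerance = 1e-9)
})

test_that("apply_transform moves selected chains and inverts exactly", {
  sys <- make_toy_complex()
  R <- random_rotation()
  tr <- structure(list(rotation = R, translation = c(1, 2, 3), rmsd = 0),
                  class = "rigid_transform")
  id <- structure(list(rotation = diag(3), translation = c(0, 0, 0),
                       rmsd = 0), class = "rigid_transform")
  expect_equal(apply_transform(sys, id), sys)
  moved <- apply_transform(sys, tr, chains = "B")
  back <- apply_transform(moved, invert_transform(tr), chains = "B")
  expect_equal(back$atoms$x, sys$atoms$x, tolerance = 1e-12)
  expect_equal(back$atoms$z, sys$atoms$z, tolerance = 1e-12)
  # pure translation shifts only the selected chain
  shift <- structure(list(rotation = diag(3), translation = c(0, 0, 5),
                          rmsd = 0), class = "rigid_transform")
  up <- apply_transform(sys, shift, chains = "B")
  selB <- sys$atoms$chain_id == "B"
  expect_equal(up$atoms$z[selB], sys$atoms$z[selB] + 5)
  expect_equal(up$atoms$z[!selB], sys$atoms$z[!selB])
})

test_that("clash detection matches the exhaustive pair scan", {
  # far-separated chains: no clash
  co1 <- matrix(rnorm(60, sd = 3), ncol = 3)
  co2 <- sweep(matrix(rnorm(60, sd = 3), ncol = 3), 2, c(50, 0, 0), "+")
  at <- rbind(point_system(co1, "A")$atoms, point_system(co2, "B")$atoms)
  at$residue_index <- seq_len(nrow(at))
  expect_equal(detect_clashes(molecular_system(at)), 0L)
  # a single constructed 1.5 A inter-chain contact
  at2 <- atom_table(c("A", "B"), 1:2, "ALA", "CA",
                    c(0, 1.5), c(0, 0), c(0, 0))
  expect_equal(detect_clashes(molecular_system(at2)), 1L)
  # random dense toy assembly agrees with the O(n^2) oracle
  set.seed(17)
  for (rep in 1:3) {
    co <- matrix(runif(3 * 300, 0, 20), ncol = 3)
    sys <- point_system(co, chain = rep(c("A", "B", "C"), each = 100))
    sys$atoms$residue_index <- seq_len(300)
    sys <- molecular_system(sys$atoms)
    expect_identical(detect_clashes(sys, cutoff = 2.0),
                     brute_clash_count(sys, cutoff = 2.0))
    expect_identical(detect_clashes(sys, cutoff = 3.5),
                     brute_clash_count(sys, cutoff = 3.5))
  }
})

test_that("interface gap is the signed min point-plane distance", {
  # interface plane z = 0, E2 body below (negative z), probes above
  plane <- expand.grid(x = c(0, 5, 10), y = c(0, 5, 10))
  e2_at <- atom_table("E", seq_len(nrow(plane) + 1), "E2B",
                      c(rep("CA", nrow(plane)), "CB"),
                      c(plane$x, 5), c(plane$y, 5), c(rep(0, nrow(plane)), -8))
  probe <- atom_table("C", 1:3, "ALA", "CA", c(1, 2, 3), c(1, 2, 3),
                      c(5, 7, 9))
  sys <- molecular_system(rbind(e2_at, probe), c(E = "E2", C = "CRBN"))
  iface <- select_atoms(sys, chain = "E2", atom_names = "CA")
  expect_equal(interface_gap(sys, iface, probe), 5, tolerance = 1e-9)
  # probe centroid on the plane -> 0; penetrating probe -> negative
  probe0 <- atom_table("C", 1, "ALA", "CA", 5, 5, 0)
  expect_equal(interface_gap(sys, iface, probe0), 0, tolerance = 1e-9)
  probe_neg <- atom_table("C", 1, "ALA", "CA", 5, 5, -3)
  expect_equal(interface_gap(sys, iface, probe_neg), -3, tolerance = 1e-9)
  # arbitrary geometry agrees with the TLS plane oracle
  set.seed(5)
  P <- matrix(rnorm(30, sd = 4), ncol = 3)
  P[, 3] <- 0.2 * P[, 1] - 0.4 * P[, 2] + rnorm(10, sd = 0.2)
  body <- colMeans(P) + c(1, -2, -9)          # off-plane E2 body atom
  Q <- matrix(rnorm(15, sd = 6), ncol = 3)
  e2b <- point_system(rbind(P, body), "E")$atoms
  pr <- point_system(Q, "C")$atoms
  pr$residue_index <- pr$residue_index + 100
  sys2 <- molecular_system(rbind(e2b, pr), c(E = "E2", C = "CRBN"))
  got <- interface_gap(sys2, e2b[1:10, ], pr)
  pl <- tls_plane(P)
  nrm <- pl$normal
  if (sum((colMeans(rbind(P, body)) - pl$centre) * nrm) > 0) nrm <- -nrm
  d <- as.numeric(sweep(Q, 2, pl$centre) %*% nrm)
  expect_equal(got, min(d), tolerance = 1e-9)
  expect_error(interface_gap(sys, e2_at[1:2, ], probe), "3 interface")
})

test_that("scaffolds classify into ring-forming, ring-open and clashing", {
  expect_equal(classify_scaffold(5, 0), "A")
  expect_equal(classify_scaffold(9.99, 0), "A")
  expect_equal(classify_scaffold(10, 0), "B")
  expect_equal(classify_scaffold(20, 0), "B")
  expect_equal(classify_scaffold(-1, 0), "C")
  expect_equal(classify_scaffold(5, 2), "C")
})

test_that("assembly superposes via the common CRBN and is idempotent", {
  full <- make_toy_complex()
  ternary <- subset_system(full, c("CRBN", "BRD4", "PROTAC"))
  scaffold0 <- subset_system(full, c("CRBN", "E2", "UB"))
  # relabel scaffold CRBN chain to avoid id collision with the ternary copy
  sc_atoms <- scaffold0$atoms
  sc_atoms$chain_id[sc_atoms$chain_id == "C"] <- "D"
  scaffold <- molecular_system(sc_atoms, c(D = "CRBN", E = "E2", U = "UB"))
  # ternary already in place: BRD4 coordinates unchanged by assembly
  out <- assemble(ternary, scaffold)
  expect_equal(select_atoms(out, chain = "BRD4"),
               select_atoms(full, chain = "BRD4"), tolerance = 1e-9)
  # pre-rotated ternary comes back onto the scaffold CRBN exactly
  R <- random_rotation()
  tr <- structure(list(rotation = R, translation = c(10, -4, 2), rmsd = 0),
                  class = "rigid_transform")
  rotated <- apply_transform(ternary, tr)
  out2 <- assemble(rotated, scaffold)
  expect_equal(select_atoms(out2, chain = "BRD4")$x,
               select_atoms(full, chain = "BRD4")$x, tolerance = 1e-9)
  # idempotence: re-assembling moves nothing
  ternary2 <- subset_system(out2, c("BRD4", "PROTAC"))
  ternary2$atoms <- rbind(ternary2$atoms,
                          within(select_atoms(out2, chain = "CRBN"),
                                 chain_id <- "C"))
  ternary2 <- molecular_system(ternary2$atoms,
                               c(B = "BRD4", P = "PROTAC", C = "CRBN"))
  out3 <- assemble(ternary2, scaffold)
  expect_equal(select_atoms(out3, chain = "BRD4")$x,
               select_atoms(out2, chain = "BRD4")$x, tolerance = 1e-9)
  expect_error(assemble(subset_system(full, "BRD4"), scaffold),
               "CRBN")
})

test_that("assembly grid enumerates every ternary x scaffold pairing", {
  g <- assembly_grid(sprintf("t%02d", 1:7), c("A1", "A2", "B1"))
  expect_equal(nrow(g), 21)
  expect_equal(anyDuplicated(paste(g$ternary_id, g$scaffold_id)), 0L)
})

test_that("minimum Lys-Gly distance matches the exhaustive scan", {
  lys <- c(K72 = 18, K76 = 12.5, K99 = 7, K102 = 16, K111 = 21,
           K112 = 25, K57 = 28, K60 = 30, K62 = 26, K91 = 24,
           K141 = 23, K155 = 27)
  sys <- make_toy_complex(lys_gly = lys)
  at <- sys$atoms
  go <- as.numeric(at[at$chain_id == "U" & at$atom_name == "O",
                      c("x", "y", "z")])
  nz <- at[at$atom_name == "NZ", ]
  d <- sqrt((nz$x - go[1])^2 + (nz$y - go[2])^2 + (nz$z - go[3])^2)
  got <- min_lys_gly_distance(sys, gly_atom = "O")
  expect_equal(got$distance, min(d), tolerance = 1e-12)
  expect_equal(got$residue, nz$residue_index[which.min(d)])
  # against the Gly C atom the requested construction distance is exact
  gotC <- min_lys_gly_distance(sys, gly_atom = "C")
  expect_equal(gotC$distance, 7, tolerance = 1e-6)
  expect_equal(gotC$residue, 99)
})

test_that("retention filter keeps clash-free assemblies within 16 A", {
  rec <- data.frame(
    ternary_id = sprintf("t%d", 1:5), scaffold_id = "A1", cluster = "A",
    clash_count = c(0, 0, 0, 3, 0),
    min_lys_gly = c(15.9, 16.0, 16.1, 8.0, 2.0))
  kept <- filter_assemblies(rec, retain_max = 16)
  expect_equal(kept$ternary_id, c("t1", "t2", "t5"))
  expect_true(all(kept$retained))
  # empty input -> empty output
  expect_equal(nrow(filter_assemblies(rec[0, ], 16)), 0)
  # infinite threshold keeps exactly the clash-free records
  all_kept <- filter_assemblies(rec, Inf)
  expect_equal(nrow(all_kept), sum(rec$clash_count == 0))
  expect_lte(nrow(kept), nrow(rec))
})
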