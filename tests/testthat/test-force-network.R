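# Nonbonded pair forces, residue force matrices, the thresholded network
# and the interaction-energy split.

mk_atom <- function(x, y, z, q = 0, s = 0, e = 0)
  atom_table("A", 1, "ALA", "CA", x, y, z, charge = q, lj_sigma = s,
             lj_epsilon = e)

test_that("pair force matches closed forms and the cutoff", {
  # opposite unit charges at 5 A: pure Coulomb attraction
  a <- mk_atom(0, 0, 0, q = 1)
  b <- mk_atom(5, 0, 0, q = -1)
  expect_equal(pair_force(a, b), -(332.0637 / 25) * 69.4786,
               tolerance = 1e-9)
  # anything beyond the 10 A short-range cutoff is zero
  b_far <- mk_atom(11, 0, 0, q = -1)
  expect_equal(pair_force(a, b_far), 0)
  expect_equal(pair_energy(a, b_far), 0)
  # pure LJ pair at the potential minimum r = 2^(1/6) sigma
  r_min <- 2^(1 / 6) * 3.4
  c1 <- mk_atom(0, 0, 0, s = 3.4, e = 0.2)
  c2 <- mk_atom(r_min, 0, 0, s = 3.4, e = 0.2)
  expect_equal(pair_force(c1, c2), 0, tolerance = 1e-9)
  # energy closed form: -332.0637/5 kcal/mol for the charge pair
  expect_equal(pair_energy(a, b), -332.0637 / 5, tolerance = 1e-12)
  # coincident atoms are a singularity
  expect_error(pair_force(a, mk_atom(0, 0, 0, q = 1)), "singularity")
})

test_that("pair force is the negative derivative of the pair energy", {
  h <- 1e-5
  at <- function(r, q2, s, e) list(a = mk_atom(0, 0, 0, q = 0.6,
                                               s = 3.2, e = 0.15),
                                   b = mk_atom(r, 0, 0, q = q2, s = s, e = e))
  for (r in c(2.5, 3.1, 4.0, 6.3, 9.9)) {
    p <- at(r, -0.4, 3.6, 0.21)
    u_plus <- pair_energy(p$a, mk_atom(r + h, 0, 0, q = -0.4, s = 3.6,
                                       e = 0.21))
    u_minus <- pair_energy(p$a, mk_atom(r - h, 0, 0, q = -0.4, s = 3.6,
                                        e = 0.21))
    numeric_force <- -(u_plus - u_minus) / (2 * h) * 69.4786
    got <- pair_force(p$a, p$b)
    expect_equal(got, numeric_force, tolerance = 1e-6)
  }
})

test_that("residue force matrix matches the exhaustive quadruple loop", {
  # 5-residue toy system with charges and LJ on every atom
  set.seed(23)
  n_res <- 5
  rows <- lapply(seq_len(n_res), function(r) {
    k <- sample(1:3, 1)
    atom_table(chain_id = if (r <= 3) "A" else "B",
               residue_index = r, residue_name = "ALA",
               atom_name = paste0("C", seq_len(k)),
               x = rnorm(k, r * 3, 1), y = rnorm(k, 0, 1),
               z = rnorm(k, 0, 1),
               charge = runif(k, -0.5, 0.5),
               lj_sigma = runif(k, 3, 3.6), lj_epsilon = runif(k, 0.05, 0.2))
  })
  sys <- molecular_system(do.call(rbind, rows))
  fm <- residue_force_matrix(sys)
  oracle <- brute_force_matrix(sys)
  expect_equal(fm$forces, oracle, tolerance = 1e-9)
  expect_equal(fm$forces, t(fm$forces))
  expect_true(all(diag(fm$forces) == 0))
  # a static two-single-atom-residue system reduces to pair_force
  two <- molecular_system(atom_table(c("A", "B"), c(1, 2), "ALA", "CA",
                                     c(0, 4), 0, 0, charge = c(1, -1)))
  fm2 <- residue_force_matrix(two)
  expect_equal(fm2$forces[1, 2],
               pair_force(two$atoms[1, ], two$atoms[2, ]),
               tolerance = 1e-12)
  # all-neutral, no-LJ system gives a zero matrix
  neutral <- point_system(matrix(rnorm(30), ncol = 3), "A")
  neutral$atoms$residue_index <- 1:10
  expect_true(all(residue_force_matrix(molecular_system(neutral$atoms))$forces == 0))
})

test_that("trajectory force matrices time-average over production frames", {
  two_at <- atom_table(c("A", "B"), c(1, 2), "ALA", "CA", c(0, 4), 0, 0,
                       charge = c(1, -1))
  # distances 4 and 6 A in two frames; average of the two pair forces
  frames <- array(0, dim = c(2, 2, 3))
  frames[1, , 1] <- c(0, 4); frames[2, , 1] <- c(0, 6)
  traj <- trajectory(frames, two_at, dt = 1)
  fm <- residue_force_matrix(traj, start_frame = 1)
  f4 <- -(332.0637 / 16) * 69.4786
  f6 <- -(332.0637 / 36) * 69.4786
  expect_equal(fm$forces[1, 2], (f4 + f6) / 2, tolerance = 1e-9)
  # start_frame discards equilibration
  fm2 <- residue_force_matrix(traj, start_frame = 2)
  expect_equal(fm2$forces[1, 2], f6, tolerance = 1e-9)
})

test_that("thresholding keeps exactly the strong pairs", {
  m <- matrix(0, 4, 4, dimnames = list(paste0("X:", 1:4), paste0("X:", 1:4)))
  m[1, 2] <- m[2, 1] <- 5       # minor repulsion: eliminated
  m[2, 3] <- m[3, 2] <- -12     # attraction beyond the band: kept
  m[3, 4] <- m[4, 3] <- 10      # exactly on the boundary: eliminated
  fm <- structure(list(residue_keys = data.frame(chain = "X",
                                                 residue_index = 1:4),
                       forces = m), class = "force_matrix")
  g <- threshold_graph(fm, 10)
  expect_equal(igraph::ecount(g), 1)
  el <- igraph::as_edgelist(g)
  expect_setequal(as.vector(el), c("X:2", "X:3"))
  expect_equal(igraph::E(g)$weight, 1 / 12)
  # edge set shrinks monotonically with the threshold
  fm_big <- make_force_matrix(15, planted_path = c(1, 8, 15), strong = 40,
                              seed = 6)
  e_lo <- igraph::ecount(threshold_graph(fm_big, 5))
  e_mid <- igraph::ecount(threshold_graph(fm_big, 10))
  e_hi <- igraph::ecount(threshold_graph(fm_big, 45))
  expect_true(e_lo >= e_mid && e_mid >= e_hi)
  expect_equal(e_hi, 0)
})

test_that("shortest force path matches exhaustive enumeration", {
  # planted chains on small graphs, several seeds
  for (seed in 1:5) {
    fm <- make_force_matrix(7, planted_path = c(1, 3, 6), strong = 30,
                            seed = seed)
    g <- threshold_graph(fm, 10)
    expect_equal(shortest_force_path(g, "X:1", "X:6"),
                 enumerate_shortest_path(fm, "X:1", "X:6"))
  }
  # two parallel paths; the stronger one wins
  m <- matrix(0, 5, 5, dimnames = list(paste0("X:", 1:5), paste0("X:", 1:5)))
  m[1, 2] <- m[2, 1] <- -50; m[2, 5] <- m[5, 2] <- -50   # strong route
  m[1, 3] <- m[3, 1] <- -15; m[3, 5] <- m[5, 3] <- -15   # weak route
  fm2 <- structure(list(residue_keys = data.frame(chain = "X",
                                                  residue_index = 1:5),
                        forces = m), class = "force_matrix")
  g2 <- threshold_graph(fm2, 10)
  expect_equal(shortest_force_path(g2, "X:1", "X:5"),
               c("X:1", "X:2", "X:5"))
  expect_equal(shortest_force_path(g2, "X:1", "X:5"),
               enumerate_shortest_path(fm2, "X:1", "X:5"))
  # single-node path and disconnected error
  expect_equal(shortest_force_path(g2, "X:4", "X:4"), "X:4")
  expect_error(shortest_force_path(g2, "X:1", "X:4"), "disconnected")
})

test_that("interaction energy equals the inter-partition pair sum", {
  # partitions beyond the cutoff: zero
  sys_far <- molecular_system(atom_table(c("A", "B"), 1:2, "ALA", "CA",
                                         c(0, 30), 0, 0, charge = c(1, -1)))
  expect_equal(interaction_energy(sys_far, list("A", "B")), 0)
  # two opposite unit charges at 5 A: closed-form Coulomb energy
  sys5 <- molecular_system(atom_table(c("A", "B"), 1:2, "ALA", "CA",
                                      c(0, 5), 0, 0, charge = c(1, -1)))
  expect_equal(interaction_energy(sys5, list("A", "B")), -332.0637 / 5,
               tolerance = 1e-12)
  # toy machinery complex: matches a brute-force inter-partition sum and
  # is symmetric in the partition
  sys <- make_toy_complex()
  parts <- list(c("CRBN", "PROTAC"), c("BRD4", "E2", "UB"))
  got <- interaction_energy(sys, parts)
  expect_equal(got, interaction_energy(sys, rev(parts)), tolerance = 1e-12)
  at <- sys$atoms
  g1 <- at$chain_id %in% c("C", "P"); g2 <- !g1
  s <- 0
  for (i in which(g1)) for (j in which(g2))
    s <- s + pair_energy(at[i, ], at[j, ])
  expect_equal(got, s, tolerance = 1e-9)
  expect_error(interaction_energy(sys, list(c("CRBN"), c("CRBN", "BRD4"))),
               "overlapping|cover")
  expect_error(interaction_energy(sys, list("CRBN", "BRD4")), "cover")
})
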