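# Independent oracles used to cross-check the implementation.  Each oracle
# deliberately takes a different algorithmic route from the code it checks.

# --- quaternion-method rigid superposition (Horn 1987) -----------------
# Returns rotation/translation mapping mobile onto reference, plus RMSD.
quaternion_superpose <- function(mobile, reference) {
  A <- as.matrix(mobile); B <- as.matrix(reference)
  ca <- colMeans(A); cb <- colMeans(B)
  A0 <- sweep(A, 2, ca); B0 <- sweep(B, 2, cb)
  S <- crossprod(A0, B0)
  N <- rbind(
    c(S[1,1]+S[2,2]+S[3,3], S[2,3]-S[3,2], S[3,1]-S[1,3], S[1,2]-S[2,1]),
    c(S[2,3]-S[3,2], S[1,1]-S[2,2]-S[3,3], S[1,2]+S[2,1], S[3,1]+S[1,3]),
    c(S[3,1]-S[1,3], S[1,2]+S[2,1], -S[1,1]+S[2,2]-S[3,3], S[2,3]+S[3,2]),
    c(S[1,2]-S[2,1], S[3,1]+S[1,3], S[2,3]+S[3,2], -S[1,1]-S[2,2]+S[3,3]))
  e <- eigen(N, symmetric = TRUE)
  q <- e$vectors[, 1]
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  R <- rbind(
    c(w*w+x*x-y*y-z*z, 2*(x*y-w*z),     2*(x*z+w*y)),
    c(2*(x*y+w*z),     w*w-x*x+y*y-z*z, 2*(y*z-w*x)),
    c(2*(x*z-w*y),     2*(y*z+w*x),     w*w-x*x-y*y+z*z))
  t_vec <- as.numeric(cb - R %*% ca)
  fitted <- sweep(A %*% t(R), 2, t_vec, "+")
  list(rotation = R, translation = t_vec,
       rmsd = sqrt(mean(rowSums((fitted - B)^2))))
}

# random proper rotation from a normalised quaternion
random_rotation <- function() {
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  rbind(
    c(w*w+x*x-y*y-z*z, 2*(x*y-w*z),     2*(x*z+w*y)),
    c(2*(x*y+w*z),     w*w-x*x+y*y-z*z, 2*(y*z-w*x)),
    c(2*(x*z-w*y),     2*(y*z+w*x),     w*w-x*x-y*y+z*z))
}

# --- exhaustive O(n^2) clash scan --------------------------------------
brute_clash_count <- function(system, cutoff = 2.0, inter_chain_only = TRUE) {
  at <- system$atoms
  co <- cbind(at$x, at$y, at$z)
  n <- nrow(co)
  count <- 0L
  for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
    if (inter_chain_only && at$chain_id[i] == at$chain_id[j]) next
    if (sum((co[i, ] - co[j, ])^2) < cutoff^2) count <- count + 1L
  }
  count
}

# --- total-least-squares plane fit by direct eigen of the scatter ------
tls_plane <- function(P) {
  ctr <- colMeans(P)
  C <- crossprod(sweep(P, 2, ctr))
  e <- eigen(C, symmetric = TRUE)
  list(centre = ctr, normal = e$vectors[, 3])
}

# --- exhaustive quadruple-loop residue force matrix --------------------
brute_force_matrix <- function(system, cutoff = 10) {
  at <- system$atoms
  rid <- paste(at$chain_id, at$residue_index, sep = ":")
  keys <- unique(rid)
  n <- length(keys)
  m <- matrix(0, n, n, dimnames = list(keys, keys))
  for (I in seq_len(n - 1)) for (J in seq(I + 1, n)) {
    ai <- which(rid == keys[I]); aj <- which(rid == keys[J])
    s <- 0
    for (a in ai) for (b in aj)
      s <- s + pair_force(at[a, ], at[b, ], cutoff = cutoff)
    m[I, J] <- m[J, I] <- s
  }
  m
}

# --- exhaustive simple-path enumeration shortest path ------------------
# weight 1/|force| on edges with |force| > threshold; lexicographic
# tie-break on the vertex-name sequence
enumerate_shortest_path <- function(fm, source, target, threshold = 10) {
  m <- fm$forces
  keys <- rownames(m)
  adj <- abs(m) > threshold
  s <- match(source, keys); t <- match(target, keys)
  best <- NULL; best_w <- Inf
  recurse <- function(path, w) {
    v <- path[length(path)]
    if (v == t) {
      key <- paste(keys[path], collapse = "\r")
      if (w < best_w - 1e-12 ||
          (abs(w - best_w) <= 1e-12 &&
           (is.null(best) || key < paste(keys[best], collapse = "\r")))) {
        best <<- path; best_w <<- w
      }
      return(invisible())
    }
    for (u in which(adj[v, ])) {
      if (u %in% path) next
      recurse(c(path, u), w + 1 / abs(m[v, u]))
    }
  }
  recurse(s, 0)
  if (is.null(best)) NULL else keys[best]
}

# --- small fixture: a system of point atoms from a coordinate matrix ---
point_system <- function(co, chain = "A", charge = 0, sigma = 0, eps = 0,
                         roles = character()) {
  n <- nrow(co)
  at <- atom_table(chain_id = rep_len(chain, n), residue_index = seq_len(n),
                   residue_name = "ALA", atom_name = "CA",
                   x = co[, 1], y = co[, 2], z = co[, 3],
                   charge = charge, lj_sigma = sigma, lj_epsilon = eps)
  molecular_system(at, roles)
}
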