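# Shared fixture builders. Everything is generated in code; no binary data.

# random proper rotation (axis-angle)
random_rotation <- function() {
  v <- stats::rnorm(3)
  v <- v / sqrt(sum(v^2))
  ang <- stats::runif(1, 0, pi)
  K <- matrix(c(0, -v[3], v[2], v[3], 0, -v[1], -v[2], v[1], 0), 3, 3, byrow = TRUE)
  diag(3) + sin(ang) * K + (1 - cos(ang)) * (K %*% K)
}

random_rigid <- function(max_shift = 20) {
  new_superposition(random_rotation(), stats::runif(3, -max_shift, max_shift))
}

# apply a rigid transform to a whole structure, keeping breaks
transform_structure <- function(s, sup) {
  xyz <- apply_superposition(s$xyz, sup)
  at <- s$atoms
  at$x <- xyz[, 1]; at$y <- xyz[, 2]; at$z <- xyz[, 3]
  new_protein_ca(at, label = s$label, breaks = s$breaks)
}

# bare protein_ca from a coordinate matrix (single chain, consecutive numbering)
structure_from_xyz <- function(xyz, label = "fixture", breaks = NULL) {
  xyz <- as.matrix(xyz)
  atoms <- data.frame(chain = "A", resno = seq_len(nrow(xyz)), insert = "",
                      resid = "ALA", x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                      stringsAsFactors = FALSE)
  new_protein_ca(atoms, label = label, breaks = breaks)
}

# ideal helix / strand C-alpha traces (same geometry the toy generator uses)
ideal_helix <- function(n, origin = c(0, 0, 0), axis = c(0, 0, 1)) {
  nsalign:::element_coords("H", n, origin, axis)
}
ideal_strand <- function(n, origin = c(0, 0, 0), axis = c(0, 0, 1)) {
  nsalign:::element_coords("E", n, origin, axis)
}

# write a minimal CA-only PDB text for parser tests
write_ca_pdb <- function(path, chains, resnos, xyz, icodes = NULL,
                         altlocs = NULL, hetatm = logical(length(resnos))) {
  n <- length(resnos)
  if (is.null(icodes)) icodes <- rep(" ", n)
  if (is.null(altlocs)) altlocs <- rep(" ", n)
  lines <- vapply(seq_len(n), function(i) {
    sprintf("%-6s%5d  CA %1sALA %1s%4d%1s   %8.3f%8.3f%8.3f  1.00  0.00           C",
            if (hetatm[i]) "HETATM" else "ATOM", i, altlocs[i], chains[i],
            resnos[i], icodes[i], xyz[i, 1], xyz[i, 2], xyz[i, 3])
  }, "")
  writeLines(c(lines, "END"), path)
  path
}

identity_pairs <- function(n) cbind(seq_len(n), seq_len(n))

# brute-force best segment: enumerate every (alpha, beta, l, dir) whose cells
# are all positive and unblocked; independent of the packaged run-scan.
brute_best_segment <- function(values, q_blocked = NULL, m_blocked = NULL,
                               mode = "forward") {
  nq <- nrow(values); nm <- ncol(values)
  if (is.null(q_blocked)) q_blocked <- rep(FALSE, nq)
  if (is.null(m_blocked)) m_blocked <- rep(FALSE, nm)
  best <- NULL
  consider <- function(alpha, beta, len, dir, score) {
    cand <- list(alpha = alpha, beta = beta, len = len, dir = dir, score = score)
    if (is.null(best)) { best <<- cand; return() }
    if (round(score - best$score, 9) > 0) { best <<- cand; return() }
    if (round(score - best$score, 9) == 0) {
      better_dir <- best$dir != "forward" && dir == "forward"
      same_dir <- dir == best$dir
      if (better_dir ||
          (same_dir && (alpha < best$alpha ||
                        (alpha == best$alpha && beta < best$beta)))) best <<- cand
    }
  }
  for (alpha in seq_len(nq)) {
    for (beta in seq_len(nm)) {
      # forward
      score <- 0
      for (l in 0:(min(nq - alpha, nm - beta))) {
        i <- alpha + l; j <- beta + l
        if (values[i, j] <= 0 || q_blocked[i] || m_blocked[j]) break
        score <- score + values[i, j]
        consider(alpha, beta, l + 1L, "forward", score)
      }
      if (mode == "mixed") {
        score <- 0
        for (l in 0:(min(nq - alpha, beta - 1L))) {
          i <- alpha + l; j <- beta - l
          if (values[i, j] <= 0 || q_blocked[i] || m_blocked[j]) break
          score <- score + values[i, j]
          if (l + 1L >= 2L) consider(alpha, beta, l + 1L, "reverse", score)
        }
      }
    }
  }
  best
}

wrap_matrix <- function(values) {
  structure(list(values = values, d_R = Inf, d0 = 1, sup = new_superposition()),
            class = "similarity_matrix")
}
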