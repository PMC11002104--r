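# Shared fixtures and independent oracles, all built in code.

# Minimal handcrafted PDB text: `residues` is a list of lists with fields
# resno, resid, chain, and an atom matrix (rows = heavy atoms).
pdb_fixture <- function(residues, path = tempfile(fileext = ".pdb"),
                        extra_lines = character(0)) {
  serial <- 0
  lines <- unlist(lapply(residues, function(r) {
    atoms <- r$atoms
    names <- if (!is.null(r$elety)) r$elety else
      c("N", "CA", "C", "O", "CB")[seq_len(nrow(atoms))]
    sapply(seq_len(nrow(atoms)), function(i) {
      serial <<- serial + 1
      sprintf("ATOM  %5d %-4s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f           %s",
              serial, paste0(" ", names[i]), r$resid, r$chain, r$resno,
              atoms[i, 1], atoms[i, 2], atoms[i, 3],
              if (is.null(r$occ)) 1 else r$occ, 0,
              substr(trimws(names[i]), 1, 1))
    })
  }))
  writeLines(c(extra_lines, lines, "END"), path)
  path
}

# Three alanines along x, one chain, one CA+CB each.
three_ala_pdb <- function(path = tempfile(fileext = ".pdb")) {
  res <- lapply(1:3, function(i) list(
    resno = i, resid = "ALA", chain = "A",
    atoms = rbind(c(4 * i, 0, 0), c(4 * i, 1.5, 0)),
    elety = c("CA", "CB")
  ))
  pdb_fixture(res, path)
}

# Independent O(N^2) scalar-loop oracle for the observed profile.
o_profile_oracle <- function(points, h, cutoff = 9, include_self = FALSE) {
  n <- nrow(points)
  o <- numeric(n)
  for (j in seq_len(n)) {
    for (i in seq_len(n)) {
      if (!include_self && i == j) next
      r <- sqrt(sum((points[i, ] - points[j, ])^2))
      if (r > cutoff) next
      x2 <- (r / cutoff)^2
      w <- 1 - 0.5 * (7 * x2 - 9 * x2^2 + 5 * x2^3 - x2^4)
      o[j] <- o[j] + (h[i] + h[j]) * max(w, 0)
    }
  }
  o / sum(o)
}

# Random well-conditioned unit for property tests.
random_unit <- function(n, seed, radius = 15) {
  set.seed(seed)
  dir <- matrix(rnorm(3 * n), ncol = 3)
  dir <- dir / sqrt(rowSums(dir^2))
  list(points = dir * radius * runif(n)^(1 / 3), h = runif(n))
}

# Random rigid-body motion applied to coordinates.
rigid_motion <- function(points, seed) {
  set.seed(seed)
  qr_q <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(qr_q) < 0) qr_q[, 1] <- -qr_q[, 1]
  sweep(points %*% qr_q, 2, runif(3, -50, 50), `+`)
}
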