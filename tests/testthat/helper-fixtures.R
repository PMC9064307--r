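# Shared fixtures, built in code.

# random discrete matrix with missing, inapplicable and polymorphic cells
random_matrix <- function(seed, ntaxa = 8, nchar = 12, p_missing = 0.15,
                          p_inapp = 0.05, p_poly = 0.08,
                          p_ordered = 0.3, max_state = 3) {
  set.seed(seed)
  cells <- matrix(NA_character_, ntaxa, nchar,
                  dimnames = list(paste0("t", seq_len(ntaxa)), NULL))
  for (j in seq_len(nchar)) {
    k <- sample(2:(max_state + 1), 1)
    for (i in seq_len(ntaxa)) {
      u <- runif(1)
      if (u < p_missing) cells[i, j] <- NA_character_
      else if (u < p_missing + p_inapp) cells[i, j] <- ""
      else if (u < p_missing + p_inapp + p_poly) {
        st <- sort(sample(0:(k - 1), 2))
        cells[i, j] <- paste(st, collapse = "/")
      } else cells[i, j] <- as.character(sample(0:(k - 1), 1))
    }
  }
  character_matrix(cells,
                   ordering = ifelse(runif(nchar) < p_ordered,
                                     "ordered", "unordered"),
                   weights = sample(c(1, 1, 1, 2), nchar, replace = TRUE))
}

# independent brute-force MORD: double loop over taxon pairs and characters
mord_oracle <- function(m) {
  n <- length(m$taxa)
  D <- matrix(NA_real_, n, n, dimnames = list(m$taxa, m$taxa))
  C <- matrix(0, n, n, dimnames = list(m$taxa, m$taxa))
  diag(D) <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    num <- den <- cw <- 0
    for (ch in seq_len(nrow(m$characters))) {
      a <- m$cells[i, ch]; b <- m$cells[j, ch]
      sa <- morphoevo:::decode_cell(a); sb <- morphoevo:::decode_cell(b)
      if (!length(sa) || !length(sb)) next
      w <- m$characters$weight[ch]
      if (m$characters$ordering[ch] == "ordered") {
        raw <- min(abs(outer(sa, sb, "-")))
        mx <- diff(range(m$characters$observed_states[[ch]]))
      } else {
        raw <- if (length(intersect(sa, sb))) 0 else 1
        mx <- 1
      }
      num <- num + w * raw; den <- den + w * mx; cw <- cw + w
    }
    if (den > 0) D[i, j] <- D[j, i] <- num / den
    C[i, j] <- C[j, i] <- cw
  }
  list(D = D, C = C)
}

# weighted squared-change parsimony oracle for Brownian ancestral states:
# minimise sum over edges of (x_parent - x_child)^2 / duration by solving
# the normal equations for the internal-node values
anc_gls_oracle <- function(tree, tipvals) {
  n <- ape::Ntip(tree)
  nn <- tree$Nnode
  A <- matrix(0, nn, nn); b <- rep(0, nn)
  for (e in seq_len(nrow(tree$edge))) {
    p <- tree$edge[e, 1] - n
    c_ <- tree$edge[e, 2]
    w <- 1 / tree$edge.length[e]
    A[p, p] <- A[p, p] + w
    if (c_ <= n) {
      b[p] <- b[p] + w * tipvals[tree$tip.label[c_]]
    } else {
      ci <- c_ - n
      A[ci, ci] <- A[ci, ci] + w
      A[p, ci] <- A[p, ci] - w
      A[ci, p] <- A[ci, p] - w
    }
  }
  solve(A, b)
}

# orthogonal Procrustes residual after centring and optimal rotation:
# min over orthogonal R of ||Y R - X||^2, R = U V' from svd(Y'X)
procrustes_residual <- function(X, Y) {
  X <- scale(X, scale = FALSE); Y <- scale(Y, scale = FALSE)
  s <- svd(crossprod(Y, X))
  sum((Y %*% s$u %*% t(s$v) - X)^2)
}
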