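# Maximum-likelihood ancestral states under the Mk model.
#
# Characters sharing a state count and ordering type are reconstructed
# together: partial likelihoods are k x n_characters matrices, and the
# transition kernel P(t) = V exp(L a t) V' is applied in the (shared)
# eigenbasis of the unit-rate generator, so a pruning pass vectorises across
# characters. Unordered characters use the equal-rates generator with total
# leave rate 1; ordered characters use the symmetric stepwise chain with
# neighbour rate 1/2. Per-character rates (changes per character per Myr)
# are ML estimates maximised over a fixed log-spaced grid.

# unit-rate generator for k states
mk_generator <- function(k, ordering) {
  if (ordering == "ordered") {
    Q <- matrix(0, k, k)
    for (i in seq_len(k - 1)) Q[i, i + 1] <- Q[i + 1, i] <- 0.5
  } else {
    Q <- matrix(1 / (k - 1), k, k)
  }
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  Q
}

# apply P(t) = V diag(exp(lambda * alpha * t)) V' columnwise with
# per-character rates alpha; L is k x nc
mk_apply <- function(eig, L, alpha, t_edge) {
  E <- exp(outer(eig$values, alpha) * t_edge)
  P <- eig$vectors %*% (E * crossprod(eig$vectors, L))
  pmax(P, 0)
}

# log-likelihood by Felsenstein pruning for one character group, vectorised
# across characters; tipL is a list (by tip id) of k x nc matrices.
# Returns list(loglik = nc vector, rootL = k x nc, scale = nc).
mk_prune <- function(tree, ages, tipL, eig, alpha) {
  n <- ape::Ntip(tree)
  nc <- ncol(tipL[[1]])
  k <- nrow(tipL[[1]])
  po <- ape::reorder.phylo(tree, "postorder")$edge
  L <- vector("list", n + tree$Nnode)
  L[seq_len(n)] <- tipL
  scale_log <- rep(0, nc)
  PL <- vector("list", nrow(po))  # P(t_e) L_child per postorder edge
  for (e in seq_len(nrow(po))) {
    p <- po[e, 1]; c_ <- po[e, 2]
    t_e <- ages[p] - ages[c_]
    PL[[e]] <- mk_apply(eig, L[[c_]], alpha, t_e)
    L[[p]] <- if (is.null(L[[p]])) PL[[e]] else L[[p]] * PL[[e]]
  }
  root <- n + 1L
  mx <- apply(L[[root]], 2, max)
  mx[mx <= 0] <- 1
  L[[root]] <- sweep(L[[root]], 2, mx, "/")
  scale_log <- scale_log + log(mx)
  list(loglik = log(colSums(L[[root]] / k)) + scale_log,
       L = L, PL = PL, po = po)
}

# marginal reconstruction (up-down pass); returns per-node k x nc arrays of
# normalised marginals for internal nodes
mk_marginals <- function(tree, ages, tipL, eig, alpha) {
  n <- ape::Ntip(tree)
  up <- mk_prune(tree, ages, tipL, eig, alpha)
  k <- nrow(tipL[[1]]); nc <- ncol(tipL[[1]])
  root <- n + 1L
  U <- vector("list", n + tree$Nnode)
  U[[root]] <- matrix(1 / k, k, nc)
  po <- up$po
  pre <- rev(seq_len(nrow(po)))
  kids_edges <- split(seq_len(nrow(po)), po[, 1])
  for (e in pre) {
    p <- po[e, 1]; c_ <- po[e, 2]
    if (c_ <= n) next
    M <- U[[p]]
    for (s in kids_edges[[as.character(p)]])
      if (s != e) M <- M * up$PL[[s]]
    t_e <- ages[p] - ages[c_]
    U[[c_]] <- mk_apply(eig, M, alpha, t_e)  # P symmetric: P' = P
    mx <- apply(U[[c_]], 2, max); mx[mx <= 0] <- 1
    U[[c_]] <- sweep(U[[c_]], 2, mx, "/")
  }
  marg <- vector("list", tree$Nnode)
  for (nd in root:(n + tree$Nnode)) {
    m_ <- U[[nd]] * up$L[[nd]]
    tot <- colSums(m_)
    tot[tot <= 0] <- 1
    marg[[nd - n]] <- sweep(m_, 2, tot, "/")
  }
  marg
}

#' Maximum-likelihood ancestral states under a single-rate Mk model
#'
#' Per character: the Mk rate is estimated by maximum likelihood (over a
#' log-spaced rate grid, or fixed via `rate`), marginal ancestral state
#' probabilities are computed on the dated tree by the pruning algorithm, and
#' each internal node is assigned its maximum-marginal-probability state
#' (ties broken toward the lower state code). Missing and inapplicable tips
#' contribute flat partial likelihoods; invariant characters are assigned
#' their constant state everywhere.
#'
#' @param m a `character_matrix`; taxa must include all tree tips.
#' @param dt a `dated_tree` (all durations > 0).
#' @param rate optional fixed rate (scalar or per-character vector,
#'   changes/character/Myr) instead of the ML estimate.
#' @param rate_grid ML search grid (default `10^seq(-3.5, 0.5, length.out =
#'   25)`).
#' @return object of class `mk_ancestral`: list with `states` (internal
#'   nodes x characters, original state codes, rows named by node id),
#'   `rates` (per-character), `loglik` (per-character), and `marginals`
#'   (per-character k x Nnode matrices, state codes as row names).
#' @export
ancestral_states_mk <- function(m, dt, rate = NULL, rate_grid = NULL) {
  tree <- dt$tree
  miss <- setdiff(tree$tip.label, m$taxa)
  if (length(miss)) stop("tree tips absent from matrix: ",
                         paste(miss, collapse = ", "))
  if (is.null(rate_grid)) rate_grid <- 10^seq(-3.5, 0.5, length.out = 25)
  n <- ape::Ntip(tree)
  nch <- n_characters(m)
  ages <- dt$ages
  cells <- m$cells[tree$tip.label, , drop = FALSE]

  obs <- m$characters$observed_states
  kvec <- vapply(obs, length, 0L)
  states <- matrix(NA_integer_, tree$Nnode, nch,
                   dimnames = list(n + seq_len(tree$Nnode), NULL))
  rates <- rep(NA_real_, nch)
  loglik <- rep(NA_real_, nch)
  marginals <- vector("list", nch)

  # invariant / empty characters
  for (j in which(kvec == 1)) {
    states[, j] <- obs[[j]]
    rates[j] <- 0
  }

  grp <- interaction(kvec, m$characters$ordering, drop = TRUE)
  for (g in levels(grp)) {
    J <- which(grp == g & kvec >= 2)
    if (!length(J)) next
    k <- kvec[J[1]]
    eig <- eigen(mk_generator(k, m$characters$ordering[J[1]]), symmetric = TRUE)
    # tip partial likelihoods
    tipL <- lapply(seq_len(n), function(i) {
      Lt <- matrix(1, k, length(J))
      for (jj in seq_along(J)) {
        st <- decode_cell(cells[i, J[jj]])
        if (length(st)) {
          v <- numeric(k)
          v[match(st, obs[[J[jj]]])] <- 1
          Lt[, jj] <- v
        }
      }
      Lt
    })
    if (is.null(rate)) {
      ll <- vapply(rate_grid, function(a)
        mk_prune(tree, ages, tipL, eig, rep(a, length(J)))$loglik,
        numeric(length(J)))
      ll <- matrix(ll, nrow = length(J))
      best <- apply(ll, 1, which.max)
      alpha <- rate_grid[best]
      loglik[J] <- ll[cbind(seq_along(J), best)]
    } else {
      alpha <- rep_len(rate, nch)[J]
      loglik[J] <- mk_prune(tree, ages, tipL, eig, alpha)$loglik
    }
    rates[J] <- alpha
    marg <- mk_marginals(tree, ages, tipL, eig, alpha)
    for (jj in seq_along(J)) {
      mm <- vapply(marg, function(x) x[, jj], numeric(k))  # k x Nnode
      dimnames(mm) <- list(obs[[J[jj]]], rownames(states))
      marginals[[J[jj]]] <- mm
      states[, J[jj]] <- obs[[J[jj]]][apply(mm, 2, which.max)]
    }
  }
  structure(list(states = states, rates = rates, loglik = loglik,
                 marginals = marginals),
            class = "mk_ancestral")
}
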