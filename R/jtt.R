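# JTT substitution model: rate matrix assembly, transition probabilities,
# and pairwise maximum-likelihood distances.

.jtt_cache <- new.env(parent = emptyenv())

# Assemble the normalized JTT rate matrix Q (mean rate 1 at equilibrium)
# and cache its symmetric eigendecomposition for fast matrix exponentials.
jtt_eigen <- function() {
  if (!is.null(.jtt_cache$eig)) return(.jtt_cache$eig)
  S <- matrix(0, 20, 20, dimnames = list(JTT_ORDER, JTT_ORDER))
  S[lower.tri(S)] <- JTT_RATES   # column-major lower-triangle layout
  S <- S + t(S)
  pi <- JTT_FREQS
  Q <- S * rep(pi, each = 20)      # Q[i, j] = S[i, j] * pi_j
  diag(Q) <- -rowSums(Q)
  Q <- Q / sum(-diag(Q) * pi)      # normalize: expected rate 1
  # symmetrize: B = diag(sqrt(pi)) Q diag(1/sqrt(pi)) is symmetric
  sp <- sqrt(pi)
  B <- Q * (sp %o% (1 / sp))
  B <- (B + t(B)) / 2
  e <- eigen(B, symmetric = TRUE)
  .jtt_cache$eig <- list(values = e$values,
                         L = e$vectors / sp,          # rows scaled by 1/sqrt(pi)
                         R = t(e$vectors * sp),       # columns scaled
                         pi = pi)
  .jtt_cache$eig
}

#' JTT transition probability matrix
#'
#' `P(t) = exp(Qt)` for the normalized JTT rate matrix (expected one
#' replacement per site per unit time at equilibrium).
#'
#' @param t Evolutionary time (expected substitutions per site).
#' @return 20 x 20 matrix, rows/cols in JTT residue order.
#' @export
jtt_pmatrix <- function(t) {
  e <- jtt_eigen()
  P <- e$L %*% (exp(e$values * t) * e$R)
  dimnames(P) <- list(JTT_ORDER, JTT_ORDER)
  # numerical cleanup: clip tiny negatives, renormalize rows
  P[P < 0] <- 0
  P / rowSums(P)
}

#' Equilibrium frequencies of the JTT model
#' @return Named numeric vector over the 20 residues (JTT order).
#' @export
jtt_frequencies <- function() JTT_FREQS

# Pairwise ML distance under JTT for two ungapped residue index vectors
# (indices into JTT_ORDER). Maximizes sum log(pi_x * P_xy(t)) over t.
jtt_ml_distance <- function(xi, yi, t_max = 20) {
  e <- jtt_eigen()
  tab <- table(factor(xi, levels = 1:20), factor(yi, levels = 1:20))
  nll <- function(t) {
    P <- jtt_pmatrix(t)
    lp <- log(pmax(P, 1e-300))
    -sum(tab * lp)
  }
  opt <- stats::optimize(nll, c(1e-8, t_max), tol = 1e-8)
  list(distance = opt$minimum, saturated = opt$minimum > 0.98 * t_max)
}

#' Evolve protein sequences under the JTT model
#'
#' Draws an ancestral sequence from the JTT equilibrium frequencies (or uses
#' the one supplied) and applies independent per-site substitution over time
#' `t` via the JTT transition matrix. Used by the synthetic-genome generator
#' so that distance-recovery tests are model-consistent.
#'
#' @param n_sites Sequence length (ignored when `ancestor` given).
#' @param t Branch length in expected substitutions per site.
#' @param ancestor Optional ancestral sequence (character string).
#' @return A character string.
#' @export
jtt_evolve <- function(n_sites = NULL, t, ancestor = NULL) {
  if (is.null(ancestor)) {
    anc_idx <- sample.int(20, n_sites, replace = TRUE, prob = JTT_FREQS)
  } else {
    anc_idx <- match(strsplit(toupper(ancestor), "", fixed = TRUE)[[1]],
                     JTT_ORDER)
    if (anyNA(anc_idx)) stop("ancestor contains non-standard residues")
  }
  P <- jtt_pmatrix(t)
  out <- vapply(anc_idx, function(i)
    sample.int(20, 1L, prob = P[i, ]), 1L)
  paste(JTT_ORDER[out], collapse = "")
}

#' Branch length giving a target expected sequence identity under JTT
#'
#' Solves `sum(pi_i * P_ii(t)) = identity` for `t`; used to plant controlled
#' divergence in synthetic families.
#'
#' @param identity Target expected identity in (0, 1).
#' @return Branch length `t`.
#' @export
jtt_time_for_identity <- function(identity) {
  stopifnot(identity > 0.06, identity < 1)
  f <- function(t) sum(JTT_FREQS * diag(jtt_pmatrix(t))) - identity
  if (identity >= 1 - 1e-12) return(0)
  stats::uniroot(f, c(1e-8, 50), tol = 1e-10)$root
}
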