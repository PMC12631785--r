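#' @title Secondary structure and accessibility features
#' @description An internal implementation of the Kabsch-Sander
#'   hydrogen-bond assignment (electrostatic model with the -0.5 kcal/mol
#'   threshold) reduced to the classic 8 states, plus relative solvent
#'   accessibility from a Shrake-Rupley sphere-point calculation.  External
#'   DSSP output can be ingested instead of the internal path.
#' @name dssp
NULL

#' Secondary-structure state letters, in one-hot column order
#' @export
DSSP_STATES <- c("H", "B", "E", "G", "I", "T", "S", "C")

# Theoretical maximum accessible surface areas (A^2) per residue type,
# used to normalize SASA into relative accessibility.
MAX_ASA <- c(ALA = 129, ARG = 274, ASN = 195, ASP = 193, CYS = 167,
             GLN = 225, GLU = 223, GLY = 104, HIS = 224, ILE = 197,
             LEU = 201, LYS = 236, MET = 224, PHE = 240, PRO = 159,
             SER = 155, THR = 172, TRP = 285, TYR = 263, VAL = 174)

VDW_RADII <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80)
vdw_radius <- function(el) {
  r <- VDW_RADII[el]
  r[is.na(r)] <- 1.80
  unname(r)
}

# Kabsch-Sander H-bond energy (kcal/mol) between donor NH(i) and acceptor
# CO(j).  H is reconstructed on the donor nitrogen.
ks_hbond_matrix <- function(V, comp) {
  L <- dim(V)[1]
  N <- V[, "N", , drop = FALSE]; dim(N) <- c(L, 3)
  C <- V[, "C", , drop = FALSE]; dim(C) <- c(L, 3)
  O <- V[, "O", , drop = FALSE]; dim(O) <- c(L, 3)
  CA <- V[, "CA", , drop = FALSE]; dim(CA) <- c(L, 3)
  H <- matrix(NA_real_, L, 3)
  for (i in 2:L) {
    if (comp[i] == "PRO") next          # proline has no amide H
    if (anyNA(N[i, ]) || anyNA(C[i - 1, ]) || anyNA(CA[i, ])) next
    d <- normalize(normalize(N[i, ] - C[i - 1, ]) + normalize(N[i, ] - CA[i, ]))
    H[i, ] <- N[i, ] + 1.01 * d
  }
  E <- matrix(Inf, L, L)
  q <- 0.084 * 332
  for (i in seq_len(L)) {
    if (anyNA(H[i, ])) next
    for (j in seq_len(L)) {
      if (abs(i - j) <= 1) next
      if (anyNA(O[j, ]) || anyNA(C[j, ])) next
      dON <- vnorm(O[j, ] - N[i, ]); dCH <- vnorm(C[j, ] - H[i, ])
      dOH <- vnorm(O[j, ] - H[i, ]); dCN <- vnorm(C[j, ] - N[i, ])
      if (dON > 7) next                 # beyond any plausible H-bond
      E[i, j] <- q * (1 / dON + 1 / dCH - 1 / dOH - 1 / dCN)
    }
  }
  E
}

# 8-state assignment: helices from n-turn patterns, strands/bridges from
# the parallel/antiparallel bridge rules, then turn and bend.
assign_secondary_structure <- function(V, comp) {
  L <- dim(V)[1]
  ss <- rep("C", L)
  if (L < 4) return(ss)
  E <- ks_hbond_matrix(V, comp)
  hb <- E < -0.5                       # hb[i, j]: NH(i) -> CO(j)
  turn <- function(n) {
    t <- rep(FALSE, L)
    idx <- seq_len(max(0, L - n))
    t[idx] <- hb[cbind(idx + n, idx)]
    t
  }
  t3 <- turn(3); t4 <- turn(4); t5 <- turn(5)
  mark <- function(ss, t, n, code) {
    for (i in which(t)) {
      if (i > 1 && t[i - 1]) {
        span <- i:min(L, i + n - 1)
        free <- ss[span] == "C" | ss[span] == code | ss[span] == "T"
        ss[span][free] <- code
      }
    }
    ss
  }
  ss <- mark(ss, t4, 4, "H")
  # bridges
  bridge <- matrix(FALSE, L, L)
  for (i in 2:(L - 1)) for (j in 2:(L - 1)) {
    if (abs(i - j) < 3) next
    par <- (hb[i, j - 1] && hb[j + 1, i]) || (hb[j, i - 1] && hb[i + 1, j])
    anti <- (hb[i, j] && hb[j, i]) || (hb[i + 1, j - 1] && hb[j + 1, i - 1])
    if (par || anti) bridge[i, j] <- TRUE
  }
  has_bridge <- rowSums(bridge) > 0
  for (i in which(has_bridge)) {
    if (ss[i] %in% c("H")) next
    ext <- (i > 1 && has_bridge[i - 1]) || (i < L && has_bridge[i + 1])
    ss[i] <- if (ext) "E" else "B"
  }
  ss <- mark(ss, t3, 3, "G")
  ss <- mark(ss, t5, 5, "I")
  # hydrogen-bonded turn
  for (n in c(3, 4, 5)) {
    t <- turn(n)
    for (i in which(t)) {
      span <- (i + 1):min(L, i + n - 1)
      ss[span][ss[span] == "C"] <- "T"
    }
  }
  # bend: CA(i-2), CA(i), CA(i+2) kink > 70 degrees
  CA <- V[, "CA", , drop = FALSE]; dim(CA) <- c(L, 3)
  for (i in 3:(L - 2)) {
    u <- CA[i, ] - CA[i - 2, ]; v <- CA[i + 2, ] - CA[i, ]
    if (anyNA(u) || anyNA(v)) next
    cosang <- sum(u * v) / (vnorm(u) * vnorm(v))
    if (acos(pmin(1, pmax(-1, cosang))) * 180 / pi > 70 && ss[i] == "C")
      ss[i] <- "S"
  }
  ss
}

# golden-spiral points on the unit sphere
sphere_points <- function(n) {
  k <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * k / n)
  theta <- pi * (1 + sqrt(5)) * k
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

# Rotate coordinates into a canonical PCA frame so that the sphere-point
# sampling below is exactly invariant under rigid motions of the input.
canonical_orientation <- function(X) {
  Xc <- sweep(X, 2, colMeans(X))
  ev <- eigen(stats::cov(Xc), symmetric = TRUE)$vectors
  Y <- Xc %*% ev
  sk <- colSums(Y^3)
  flip <- ifelse(sk < 0, -1, 1)
  ev <- sweep(ev, 2, flip, "*")
  if (det(ev) < 0) ev[, which.min(abs(sk))] <- -ev[, which.min(abs(sk))]
  Xc %*% ev
}

# Shrake-Rupley SASA per atom; returns per-residue sums.
residue_sasa <- function(chain, n_points = 92, probe = 1.4) {
  at <- chain$atoms
  X <- canonical_orientation(cbind(at$x, at$y, at$z))
  r <- vdw_radius(at$element) + probe
  n <- nrow(X)
  pts <- sphere_points(n_points)
  sasa <- numeric(n)
  cut <- max(r) * 2
  nb <- brute_pairs_within(X, X, cut)
  nb <- nb[nb$i != nb$j, ]
  nb_by_i <- split(nb$j, nb$i)
  for (i in seq_len(n)) {
    P <- sweep(pts * r[i], 2, X[i, ], "+")
    js <- nb_by_i[[as.character(i)]]
    acc <- rep(TRUE, n_points)
    if (!is.null(js)) {
      for (j in js) {
        d2 <- (P[, 1] - X[j, 1])^2 + (P[, 2] - X[j, 2])^2 +
              (P[, 3] - X[j, 3])^2
        acc <- acc & (d2 > r[j]^2)
        if (!any(acc)) break
      }
    }
    sasa[i] <- 4 * pi * r[i]^2 * mean(acc)
  }
  as.numeric(tapply(sasa, factor(at$res_index, levels = seq_len(nrow(chain$res)) - 1L),
                    sum, default = 0))
}

#' Secondary-structure and accessibility node features
#'
#' 8-state one-hot secondary structure (order H, B, E, G, I, T, S, C) from
#' an internal Kabsch-Sander hydrogen-bond assignment, plus relative
#' solvent accessibility in `[0, 1]` — 9 columns total.  Chains shorter
#' than 4 residues are assigned all-coil.  Alternatively, a parsed
#' external DSSP table can be supplied.
#'
#' @param chain a `residue_chain` with virtual atoms computed.
#' @param external optional data.frame with columns `ss` (one of the 8
#'   state letters) and `rsa` in `[0,1]`, one row per residue, as parsed
#'   from an external DSSP run; used verbatim when given.
#' @return L x 9 numeric matrix.
#' @export
dssp_features <- function(chain, external = NULL) {
  stopifnot(inherits(chain, "residue_chain"))
  L <- nrow(chain$res)
  if (!is.null(external)) {
    stopifnot(nrow(external) == L)
    ss <- external$ss; rsa <- external$rsa
  } else {
    if (is.null(chain$virtual)) chain <- compute_virtual_atoms(chain)
    ss <- if (L < 4) rep("C", L)
          else assign_secondary_structure(chain$virtual, chain$res$comp)
    max_asa <- MAX_ASA[chain$res$comp]
    max_asa[is.na(max_asa)] <- 200
    rsa <- pmin(1, pmax(0, residue_sasa(chain) / max_asa))
  }
  onehot <- matrix(0, L, 8, dimnames = list(NULL, DSSP_STATES))
  onehot[cbind(seq_len(L), match(ss, DSSP_STATES))] <- 1
  cbind(onehot, rsa = rsa)
}
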