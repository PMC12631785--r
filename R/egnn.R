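#' @title Equivariant graph neural network
#' @description A four-layer EGNN operating on CA coordinates plus node
#'   and edge features, with one small MLP + sigmoid head per binding
#'   task.  Message updates use node features, neighbour messages and
#'   relative positions; feature updates are therefore invariant, and the
#'   optional coordinate updates equivariant, under rotations and
#'   translations.  Forward and backward passes are implemented directly
#'   on matrices (no autodiff dependency); gradients are validated against
#'   finite differences in the test suite.
#' @name egnn_model
NULL

#' EGNN model configuration
#'
#' @param num_layers EGNN layers (default 4).
#' @param hidden_dim node feature width inside the network (default 128).
#' @param message_dim message width (default 128).
#' @param head_hidden hidden width of each task head MLP (default 64).
#' @param node_dim,edge_dim expected input feature widths.
#' @param n_tasks number of sigmoid heads (default 5).
#' @param aggregation `"mean"` (degree-normalized, default) or `"sum"`.
#' @param update_coordinates update coordinates between layers (standard
#'   EGNN); predictions use only node features, so invariance holds either
#'   way.
#' @param dropout dropout rate on node features during training.
#' @param seed initialization seed (recorded in checkpoints).
#' @export
egnn_config <- function(num_layers = 4L, hidden_dim = 128L,
                        message_dim = 128L, head_hidden = 64L,
                        node_dim = 2247L, edge_dim = 450L, n_tasks = 5L,
                        aggregation = c("mean", "sum"),
                        update_coordinates = TRUE, dropout = 0,
                        seed = 42L) {
  aggregation <- match.arg(aggregation)
  stopifnot(num_layers >= 1, hidden_dim > 0, message_dim > 0,
            head_hidden > 0, dropout >= 0, dropout < 1)
  structure(list(num_layers = as.integer(num_layers),
                 hidden_dim = as.integer(hidden_dim),
                 message_dim = as.integer(message_dim),
                 head_hidden = as.integer(head_hidden),
                 node_dim = as.integer(node_dim),
                 edge_dim = as.integer(edge_dim),
                 n_tasks = as.integer(n_tasks),
                 aggregation = aggregation,
                 update_coordinates = isTRUE(update_coordinates),
                 dropout = dropout, seed = as.integer(seed)),
            class = "egnn_config")
}

silu <- function(x) x / (1 + exp(-x))
silu_grad <- function(x) {
  s <- 1 / (1 + exp(-x))
  s * (1 + x * (1 - s))
}
sigmoid <- function(x) 1 / (1 + exp(-x))

lin_init <- function(n_in, n_out, gain = 1) {
  s <- gain / sqrt(n_in)
  list(W = matrix(stats::runif(n_in * n_out, -s, s), n_in, n_out),
       b = numeric(n_out))
}

#' Initialize an EGNN model
#'
#' Fan-in uniform initialization from the config seed; the coordinate
#' MLP's output layer uses a small gain to keep early coordinate updates
#' tame.
#'
#' @param cfg an [egnn_config()].
#' @return an `egnn_model` (nested parameter list + config).
#' @export
egnn_model <- function(cfg = egnn_config()) {
  stopifnot(inherits(cfg, "egnn_config"))
  h <- cfg$hidden_dim; m <- cfg$message_dim
  params <- with_seed(cfg$seed, function() {
    p <- list(input = lin_init(cfg$node_dim, h),
              edge_proj = lin_init(cfg$edge_dim, m),
              layers = vector("list", cfg$num_layers),
              heads = vector("list", cfg$n_tasks))
    for (l in seq_len(cfg$num_layers)) {
      p$layers[[l]] <- list(
        e1 = lin_init(2 * h + 1 + m, m), e2 = lin_init(m, m),
        x1 = lin_init(m, m), x2 = lin_init(m, 1, gain = 0.1),
        h1 = lin_init(h + m, h), h2 = lin_init(h, h))
    }
    for (t in seq_len(cfg$n_tasks)) {
      p$heads[[t]] <- list(H1 = lin_init(h, cfg$head_hidden),
                           H2 = lin_init(cfg$head_hidden, 1))
    }
    p
  })
  structure(list(config = cfg, params = params), class = "egnn_model")
}

#' @export
print.egnn_model <- function(x, ...) {
  cat("<egnn_model>", x$config$num_layers, "layers, hidden",
      x$config$hidden_dim, "- input", x$config$node_dim, "/",
      x$config$edge_dim, "-", x$config$n_tasks, "task heads\n")
  invisible(x)
}

affine <- function(X, lin) sweep(X %*% lin$W, 2, lin$b, "+")

# scatter-add rows of M into an L-row accumulator by index
scatter_rows <- function(M, idx, L) {
  out <- matrix(0, L, ncol(M))
  r <- rowsum(M, idx)
  out[as.integer(rownames(r)), ] <- r
  out
}

#' Forward pass of the EGNN
#'
#' @param model an `egnn_model`.
#' @param graph a `residue_graph` (feature widths must match the config).
#' @param training apply dropout (if configured) with the current RNG.
#' @param keep_cache retain intermediates for [egnn_backward()].
#' @return list with `probs` (L x n_tasks, open interval (0,1)), `logits`,
#'   `coords_out`, and `cache` when requested.
#' @export
egnn_forward <- function(model, graph, training = FALSE, keep_cache = FALSE) {
  cfg <- model$config; P <- model$params
  X <- graph$node_features; EF <- graph$edge_features
  if (ncol(X) != cfg$node_dim) {
    stop("node feature width ", ncol(X), " does not match model input ",
         cfg$node_dim)
  }
  if (ncol(EF) != cfg$edge_dim) {
    stop("edge feature width ", ncol(EF), " does not match model input ",
         cfg$edge_dim)
  }
  if (!all(is.finite(X)) || !all(is.finite(EF)) ||
      !all(is.finite(graph$coords))) {
    stop("non-finite values in graph inputs")
  }
  L <- nrow(X); hdim <- cfg$hidden_dim
  src <- graph$edges[, 1]; dst <- graph$edges[, 2]
  h <- affine(X, P$input)
  eproj <- affine(EF, P$edge_proj)
  x <- graph$coords
  deg <- tabulate(src, nbins = L)
  Cdeg <- ifelse(deg > 0, 1 / deg, 0)
  cache <- if (keep_cache) list(X = X, EF = EF, src = src, dst = dst,
                                deg = deg, Cdeg = Cdeg, eproj = eproj,
                                layers = vector("list", cfg$num_layers))
           else NULL
  for (l in seq_len(cfg$num_layers)) {
    lp <- P$layers[[l]]
    D <- x[src, , drop = FALSE] - x[dst, , drop = FALSE]
    d2 <- rowSums(D^2)
    A <- cbind(h[src, , drop = FALSE], h[dst, , drop = FALSE], d2, eproj)
    dimnames(A) <- NULL
    z1 <- affine(A, lp$e1); s1 <- silu(z1)
    z2 <- affine(s1, lp$e2); msg <- silu(z2)
    u1 <- affine(msg, lp$x1); t1 <- silu(u1)
    phix <- affine(t1, lp$x2)            # E x 1
    if (cfg$update_coordinates) {
      xupd <- scatter_rows(D * as.vector(phix), src, L)
      x_new <- x + xupd * Cdeg
    } else {
      x_new <- x
    }
    agg <- scatter_rows(msg, src, L)
    if (cfg$aggregation == "mean") agg <- agg * Cdeg
    B <- cbind(h, agg)
    v1 <- affine(B, lp$h1); sh <- silu(v1)
    z <- affine(sh, lp$h2)
    h_new <- h + z
    drop_mask <- NULL
    if (training && cfg$dropout > 0) {
      drop_mask <- matrix(stats::rbinom(L * hdim, 1, 1 - cfg$dropout) /
                            (1 - cfg$dropout), L, hdim)
      h_new <- h_new * drop_mask
    }
    if (keep_cache) {
      cache$layers[[l]] <- list(h = h, x = x, D = D, d2 = d2, A = A,
                                z1 = z1, s1 = s1, z2 = z2, msg = msg,
                                u1 = u1, t1 = t1, phix = phix, agg = agg,
                                B = B, v1 = v1, sh = sh,
                                drop_mask = drop_mask)
    }
    h <- h_new; x <- x_new
  }
  logits <- matrix(0, L, cfg$n_tasks)
  head_cache <- vector("list", cfg$n_tasks)
  for (t in seq_len(cfg$n_tasks)) {
    hp <- P$heads[[t]]
    q1 <- affine(h, hp$H1); sq <- silu(q1)
    logits[, t] <- affine(sq, hp$H2)
    if (keep_cache) head_cache[[t]] <- list(q1 = q1, sq = sq)
  }
  if (keep_cache) { cache$h_top <- h; cache$heads <- head_cache }
  if (!all(is.finite(logits))) stop("non-finite logits in forward pass")
  list(probs = sigmoid(logits), logits = logits, coords_out = x,
       cache = cache)
}

#' Backward pass: gradients of a scalar loss w.r.t. all parameters
#'
#' @param model an `egnn_model`.
#' @param cache the cache from `egnn_forward(..., keep_cache = TRUE)`.
#' @param dlogits L x n_tasks gradient of the loss w.r.t. the logits.
#' @return gradient list with the same structure as `model$params`.
#' @export
egnn_backward <- function(model, cache, dlogits) {
  cfg <- model$config; P <- model$params
  L <- nrow(dlogits); hdim <- cfg$hidden_dim; m <- cfg$message_dim
  src <- cache$src; dst <- cache$dst
  G <- list(input = NULL, edge_proj = NULL,
            layers = vector("list", cfg$num_layers),
            heads = vector("list", cfg$n_tasks))
  h_top <- cache$h_top
  dh <- matrix(0, L, hdim)
  for (t in seq_len(cfg$n_tasks)) {
    hp <- P$heads[[t]]; hc <- cache$heads[[t]]
    dq <- dlogits[, t, drop = FALSE]
    dW2 <- t(hc$sq) %*% dq; db2 <- colSums(dq)
    dsq <- dq %*% t(hp$H2$W)
    dq1 <- dsq * silu_grad(hc$q1)
    dW1 <- t(h_top) %*% dq1; db1 <- colSums(dq1)
    dh <- dh + dq1 %*% t(hp$H1$W)
    G$heads[[t]] <- list(H1 = list(W = dW1, b = db1),
                         H2 = list(W = dW2, b = db2))
  }
  dx <- matrix(0, L, 3)
  deproj <- matrix(0, nrow(cache$eproj), m)
  Cdeg <- cache$Cdeg
  for (l in rev(seq_len(cfg$num_layers))) {
    lp <- P$layers[[l]]; lc <- cache$layers[[l]]
    if (!is.null(lc$drop_mask)) dh <- dh * lc$drop_mask
    # node MLP
    dz <- dh
    dWh2 <- t(lc$sh) %*% dz; dbh2 <- colSums(dz)
    dsh <- dz %*% t(lp$h2$W)
    dv1 <- dsh * silu_grad(lc$v1)
    dWh1 <- t(lc$B) %*% dv1; dbh1 <- colSums(dv1)
    dB <- dv1 %*% t(lp$h1$W)
    dh_new <- dh + dB[, seq_len(hdim), drop = FALSE]   # residual + h slice
    dagg <- dB[, hdim + seq_len(m), drop = FALSE]
    dmsg <- dagg[src, , drop = FALSE]
    if (cfg$aggregation == "mean") dmsg <- dmsg * Cdeg[src]
    # coordinate path
    dphix <- matrix(0, length(src), 1)
    dD <- matrix(0, length(src), 3)
    dx_new <- dx
    if (cfg$update_coordinates) {
      dx_src <- dx[src, , drop = FALSE] * Cdeg[src]
      dphix[, 1] <- rowSums(dx_src * lc$D)
      dD <- dx_src * as.vector(lc$phix)
    }
    dWx2 <- t(lc$t1) %*% dphix; dbx2 <- colSums(dphix)
    dt1 <- dphix %*% t(lp$x2$W)
    du1 <- dt1 * silu_grad(lc$u1)
    dWx1 <- t(lc$msg) %*% du1; dbx1 <- colSums(du1)
    dmsg <- dmsg + du1 %*% t(lp$x1$W)
    # edge MLP
    dz2 <- dmsg * silu_grad(lc$z2)
    dWe2 <- t(lc$s1) %*% dz2; dbe2 <- colSums(dz2)
    ds1 <- dz2 %*% t(lp$e2$W)
    dz1 <- ds1 * silu_grad(lc$z1)
    dWe1 <- t(lc$A) %*% dz1; dbe1 <- colSums(dz1)
    dA <- dz1 %*% t(lp$e1$W)
    dh_new <- dh_new + scatter_rows(dA[, seq_len(hdim), drop = FALSE], src, L) +
      scatter_rows(dA[, hdim + seq_len(hdim), drop = FALSE], dst, L)
    dd2 <- dA[, 2 * hdim + 1]
    deproj <- deproj + dA[, 2 * hdim + 1 + seq_len(m), drop = FALSE]
    dD <- dD + 2 * lc$D * dd2
    dx_new <- dx_new + scatter_rows(dD, src, L) - scatter_rows(dD, dst, L)
    G$layers[[l]] <- list(
      e1 = list(W = dWe1, b = dbe1), e2 = list(W = dWe2, b = dbe2),
      x1 = list(W = dWx1, b = dbx1), x2 = list(W = dWx2, b = dbx2),
      h1 = list(W = dWh1, b = dbh1), h2 = list(W = dWh2, b = dbh2))
    dh <- dh_new; dx <- dx_new
  }
  G$input <- list(W = t(cache$X) %*% dh, b = colSums(dh))
  G$edge_proj <- list(W = t(cache$EF) %*% deproj, b = colSums(deproj))
  G
}

#' Predict binding probabilities for a residue graph
#'
#' @param model an `egnn_model`.
#' @param graph a `residue_graph`.
#' @param threshold decision threshold for binary calls (strictly greater
#'   than; default 0.5).
#' @return a `prediction_result`: `chain_id`, `probs` (L x 5 in (0,1)),
#'   `calls` (0/1), `auth_seq`, task order protein/nucleic/ligand/ion/lipid.
#' @export
predict_graph <- function(model, graph, threshold = 0.5) {
  fw <- egnn_forward(model, graph)
  probs <- fw$probs
  colnames(probs) <- TASKS[seq_len(ncol(probs))]
  structure(list(chain_id = graph$chain_id, probs = probs,
                 calls = (probs > threshold) * 1L,
                 auth_seq = graph$auth_seq, threshold = threshold),
            class = "prediction_result")
}

#' @export
print.prediction_result <- function(x, ...) {
  cat("<prediction_result>", x$chain_id, "-", nrow(x$probs),
      "residues; calls:",
      paste(colnames(x$probs), colSums(x$calls), sep = "=", collapse = " "),
      "\n")
  invisible(x)
}

CHECKPOINT_VERSION <- 1L

config_hash <- function(cfg) {
  text_md5(jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE, digits = NA))
}

pack_params <- function(p) {
  rapply(p, function(x) {
    if (is.matrix(x)) list(dim = dim(x), data = as.numeric(x))
    else list(dim = length(x), data = as.numeric(x))
  }, classes = c("matrix", "numeric"), how = "replace")
}

unpack_params <- function(p) {
  walk <- function(node) {
    if (is.list(node) && identical(sort(names(node)), c("data", "dim"))) {
      d <- unlist(node$dim)
      v <- as.numeric(unlist(node$data))
      if (length(d) == 2) matrix(v, d[1], d[2]) else v
    } else if (is.list(node)) {
      lapply(node, walk)
    } else node
  }
  walk(p)
}

#' Save a model checkpoint
#'
#' Single-file JSON archive: format version, config (plus its hash), seed
#' and all parameter arrays at full precision.
#'
#' @param model an `egnn_model`.
#' @param path output file.
#' @export
save_checkpoint <- function(model, path) {
  obj <- list(format = "resbind-egnn-checkpoint",
              version = CHECKPOINT_VERSION,
              config = unclass(model$config),
              config_hash = config_hash(model$config),
              params = pack_params(model$params))
  # I(17) significant digits: exact double round trip
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' Load a model checkpoint
#'
#' @param path checkpoint file from [save_checkpoint()].
#' @param config optional `egnn_config`; when given, the checkpoint must
#'   have been written with an identical config (hash comparison).
#' @return an `egnn_model` whose forward outputs equal the saved model's.
#' @export
load_checkpoint <- function(path, config = NULL) {
  obj <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE,
                                      simplifyDataFrame = FALSE,
                                      simplifyMatrix = FALSE),
                  error = function(e) NULL)
  if (is.null(obj) || !identical(obj$format, "resbind-egnn-checkpoint")) {
    stop("not a readable checkpoint file: ", path)
  }
  if (!identical(as.integer(obj$version), CHECKPOINT_VERSION)) {
    stop("checkpoint format version ", obj$version,
         " not supported (expected ", CHECKPOINT_VERSION, ")")
  }
  cfg <- do.call(egnn_config, obj$config[setdiff(names(obj$config), NULL)])
  if (!identical(config_hash(cfg), obj$config_hash)) {
    stop("checkpoint config hash mismatch; file corrupt or edited")
  }
  if (!is.null(config) && !identical(config_hash(config), obj$config_hash)) {
    stop("checkpoint was written with a different config")
  }
  model <- structure(list(config = cfg, params = unpack_params(obj$params)),
                     class = "egnn_model")
  model
}
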