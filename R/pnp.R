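#' Assemble the combined network matrix W
#'
#' Collects every identified parameter into one block matrix: rows are all
#' network nodes ordered by class (proteins, genes, lncRNAs, miRNAs; within
#' a class, lexicographically), columns are the regulator nodes
#' (transcription factors, then lncRNAs, then miRNAs). A cell holds the
#' estimated parameter of the identified edge from the column regulator to
#' the row node and is exactly zero where no edge was retained. Protein
#' rows hold interaction parameters in the columns of their TF interaction
#' partners; protein-protein edges whose partner is not a TF have no column
#' to occupy and are skipped (they remain part of the identified network).
#'
#' @param net A `gw_identified` network.
#' @return An object of class `gw_W`: `values` (numeric matrix), `row_kinds`,
#'   `block_map` (row/column index ranges per class).
#' @export
assemble_W <- function(net) {
  stopifnot(inherits(net, "gw_identified"))
  kinds <- net$node_kinds
  ids <- names(kinds)
  rows <- c(sort(ids[kinds %in% c("protein", "tf")]),
            sort(ids[kinds == "gene"]),
            sort(ids[kinds == "lncrna"]),
            sort(ids[kinds == "mirna"]))
  cols <- c(sort(ids[kinds == "tf"]),
            sort(ids[kinds == "lncrna"]),
            sort(ids[kinds == "mirna"]))
  W <- matrix(0, nrow = length(rows), ncol = length(cols),
              dimnames = list(rows, cols))
  edges <- net$edges
  for (i in seq_len(nrow(edges))) {
    src <- edges$source[i]
    tgt <- edges$target[i]
    type <- edges$edge_type[i]
    src_kind <- kinds[[src]]
    tgt_ok <- tgt %in% rows
    if (!tgt_ok || !src_kind %in% edge_source_kind(type)) {
      stop_gw("edge %s -> %s (%s) has kind-incompatible endpoints",
              src, tgt, type)
    }
    if (type == "pp" && src_kind != "tf") next  # no column for this partner
    W[tgt, src] <- edges$parameter[i]
  }
  structure(
    list(
      values = W,
      row_kinds = kinds[rows],
      block_map = list(
        rows = list(proteins = which(kinds[rows] %in% c("protein", "tf")),
                    genes = which(kinds[rows] == "gene"),
                    lncrnas = which(kinds[rows] == "lncrna"),
                    mirnas = which(kinds[rows] == "mirna")),
        cols = list(tfs = which(kinds[cols] == "tf"),
                    lncrnas = which(kinds[cols] == "lncrna"),
                    mirnas = which(kinds[cols] == "mirna"))
      )
    ),
    class = "gw_W"
  )
}

#' Principal network projection
#'
#' Decomposes the combined network matrix by singular value decomposition,
#' computes each singular value's eigen expression fraction (its squared
#' share of the total squared singular-value energy), selects the minimal
#' number X of leading singular vectors whose cumulative fraction reaches
#' the energy threshold, projects every node (row of W) onto those top X
#' right singular vectors and ranks nodes by the 2-norm of their
#' projections. Nodes with projection norm below 1e-12 are flagged as
#' insignificant (nearly independent of the principal network structure)
#' but kept in the ranking.
#'
#' @param W A `gw_W` combined network matrix.
#' @param threshold Energy threshold in `(0, 1]`; default 0.85.
#' @param K Core size: number of top-ranked nodes forming the core network
#'   (default 6000, far above desk-scale node counts, i.e. "all").
#' @return An object of class `gw_pnp`: `singular_values`,
#'   `eigen_fractions`, `X`, `projections` (node x X matrix),
#'   `ranking` (data.frame: node, kind, Q, rank, insignificant, in_core),
#'   `threshold`, `K`.
#' @export
pnp <- function(W, threshold = 0.85, K = 6000L) {
  stopifnot(inherits(W, "gw_W"))
  if (threshold <= 0 || threshold > 1) stop_gw("threshold must be in (0, 1]")
  K <- check_count(K, "K")
  M <- W$values
  if (all(M == 0)) stop_gw("no identified network energy: W is all zero")
  sv <- svd(M)
  sigma <- sv$d
  ex <- sigma^2 / sum(sigma^2)
  X <- which(cumsum(ex) >= threshold - 1e-15)[1]
  P <- M %*% sv$v[, seq_len(X), drop = FALSE]
  Q <- sqrt(rowSums(P^2))
  ord <- order(-Q, rownames(M))   # ties broken lexicographically by node id
  ranking <- data.frame(
    node = rownames(M)[ord],
    kind = unname(W$row_kinds[ord]),
    Q = Q[ord],
    rank = seq_along(ord),
    insignificant = Q[ord] < 1e-12,
    stringsAsFactors = FALSE
  )
  ranking$in_core <- ranking$rank <= min(K, nrow(ranking))
  structure(
    list(singular_values = sigma, eigen_fractions = ex, X = X,
         projections = P, projection_norms = Q, ranking = ranking,
         threshold = threshold, K = K, svd = sv),
    class = "gw_pnp"
  )
}

#' Extract the core network
#'
#' Returns the subnetwork of the identified network induced by the top-K
#' nodes of the projection ranking: edges whose endpoints are both in the
#' core, plus the ranked node table.
#'
#' @param net A `gw_identified` network.
#' @param result A `gw_pnp` projection result for the same network.
#' @return A list with `nodes` (ranked core node table), `edges` (induced
#'   edge list) and `K`.
#' @export
extract_core <- function(net, result) {
  stopifnot(inherits(net, "gw_identified"), inherits(result, "gw_pnp"))
  core_nodes <- result$ranking$node[result$ranking$in_core]
  edges <- net$edges[net$edges$source %in% core_nodes &
                       net$edges$target %in% core_nodes, , drop = FALSE]
  rownames(edges) <- NULL
  list(nodes = result$ranking[result$ranking$in_core, , drop = FALSE],
       edges = edges, K = result$K)
}
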