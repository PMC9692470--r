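# All tabular I/O is UTF-8 TSV; floats are written with 9 significant
# digits so write/read round trips are stable at test tolerance.

fmt_num <- function(x) formatC(x, digits = 9, format = "g")

#' Write / read an expression dataset
#'
#' The matrix is written as a TSV with node ids in the first column and a
#' header row of sample ids; node kinds go to a sidecar TSV (`<path>` with
#' `.kinds.tsv` appended) with columns `node`, `kind`.
#'
#' @param data A `gw_expression`.
#' @param path Output TSV path.
#' @return `write_expression` returns `path` invisibly; `read_expression`
#'   returns a `gw_expression`.
#' @export
write_expression <- function(data, path) {
  stopifnot(inherits(data, "gw_expression"))
  tab <- data.frame(node = data$node_ids,
                    apply(data$values, 2, fmt_num),
                    stringsAsFactors = FALSE, check.names = FALSE)
  colnames(tab) <- c("node", data$sample_ids)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  kinds <- data.frame(node = data$node_ids,
                      kind = unname(data$node_kinds[data$node_ids]))
  utils::write.table(kinds, paste0(path, ".kinds.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_expression
#' @export
read_expression <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 2) stop_gw("no samples in '%s'", path)
  if (anyDuplicated(tab$node)) {
    stop_gw("duplicated node id '%s' in '%s'",
            tab$node[duplicated(tab$node)][1], path)
  }
  values <- as.matrix(tab[, -1, drop = FALSE])
  if (!is.numeric(values)) {
    bad <- which(!apply(tab[, -1, drop = FALSE], 1, function(r)
      all(!is.na(suppressWarnings(as.numeric(r))))))[1]
    stop_gw("non-numeric expression value at line %d of '%s'", bad + 1L, path)
  }
  rownames(values) <- tab$node
  kinds_path <- paste0(path, ".kinds.tsv")
  if (!file.exists(kinds_path)) stop_gw("missing kinds sidecar '%s'", kinds_path)
  ktab <- utils::read.delim(kinds_path, stringsAsFactors = FALSE)
  kinds <- stats::setNames(ktab$kind, ktab$node)
  missing <- setdiff(tab$node, names(kinds))
  if (length(missing) > 0) {
    stop_gw("node(s) missing from kinds sidecar: %s",
            paste(missing, collapse = ", "))
  }
  structure(
    list(values = values, node_ids = tab$node, node_kinds = kinds[tab$node],
         sample_ids = colnames(values)),
    class = "gw_expression"
  )
}

#' Write / read a network edge list
#'
#' Edge lists are TSVs with columns `source`, `target`, `edge_type`
#' (`pp | tf_reg | lnc_reg | mir_reg`) and, for parameterized (truth or
#' identified) networks, `parameter`. A node-kind table is required to
#' validate edge types on read.
#'
#' @param net A `gw_candidate`, `gw_truth` or `gw_identified` network, or
#'   any list with an `edges` data.frame.
#' @param path Output TSV path.
#' @param node_kinds Named character vector of node kinds (read side).
#' @return `write_network` returns `path` invisibly; `read_network` a
#'   `gw_candidate`-shaped object (with `parameter` column if present).
#' @export
write_network <- function(net, path) {
  edges <- net$edges
  if ("parameter" %in% names(edges)) edges$parameter <- fmt_num(edges$parameter)
  utils::write.table(edges, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_network
#' @export
read_network <- function(path, node_kinds) {
  edges <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (nrow(edges) > 0) {
    bad_type <- setdiff(unique(edges$edge_type), EDGE_TYPES)
    if (length(bad_type) > 0) {
      stop_gw("unknown edge_type(s): %s", paste(bad_type, collapse = ", "))
    }
    dangling <- setdiff(unique(c(edges$source, edges$target)), names(node_kinds))
    if (length(dangling) > 0) {
      stop_gw("edge(s) reference unknown node(s): %s",
              paste(dangling, collapse = ", "))
    }
    for (ty in unique(edges$edge_type)) {
      src_kinds <- node_kinds[edges$source[edges$edge_type == ty]]
      if (!all(src_kinds %in% edge_source_kind(ty))) {
        stop_gw("edge_type '%s' with incompatible source kind", ty)
      }
    }
  }
  structure(list(edges = edges, node_kinds = node_kinds),
            class = "gw_candidate")
}

#' Pipeline configuration
#'
#' One structured configuration drives an end-to-end run; unknown keys are
#' rejected. Component configurations use their own constructors'
#' defaults unless overridden.
#'
#' @param seed Global seed; every stage derives its randomness from it.
#' @param simulation A [simulation_config()] (its `seed` is overridden by
#'   the global seed).
#' @param dti_data A [dti_config()] (seed overridden likewise).
#' @param training A [training_config()] (seed overridden likewise).
#' @param pnp_threshold Energy threshold for the projection step.
#' @param core_size Core network size K.
#' @param disease Disease context for the drug-design stage.
#' @param s_max Sensitivity bound for the drug filter.
#' @return An object of class `gw_pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L,
                            simulation = simulation_config(),
                            dti_data = dti_config(
                              n_positive = 300L, n_negative = 400L),
                            training = training_config(
                              hidden_sizes = c(32L, 16L), epochs = 40L),
                            pnp_threshold = 0.85, core_size = 6000L,
                            disease = "MIBC", s_max = 3) {
  seed <- check_count(seed, "seed", min = 0L)
  simulation$seed <- seed
  dti_data$seed <- seed + 1000L
  training$seed <- seed + 2000L
  structure(
    list(seed = seed, simulation = simulation, dti_data = dti_data,
         training = training,
         pnp_threshold = check_fraction(pnp_threshold, "pnp_threshold"),
         core_size = check_count(core_size, "core_size"),
         disease = disease, s_max = as.numeric(s_max)),
    class = "gw_pipeline_config"
  )
}

#' Run the full pipeline
#'
#' Executes simulate -> identify -> project/extract-core -> train the
#' interaction classifier (on a synthetic labeled dataset) -> design the
#' drug combination (on the bundled drug-property tables), writing every
#' stage's outputs and a reproducibility manifest into `out_dir`.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if absent).
#' @return Invisibly, a list with every stage's in-memory result and the
#'   manifest.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir) {
  stopifnot(inherits(config, "gw_pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop_gw("pipeline stage '%s' failed: %s", name, conditionMessage(e))
    })
  }

  nets <- stage("simulate", generate_candidate_network(config$simulation))
  expr_data <- stage("simulate", simulate_expression(nets$truth, config$simulation))
  write_expression(expr_data, file.path(out_dir, "expression.tsv"))
  write_network(nets$candidate, file.path(out_dir, "candidate_network.tsv"))
  write_network(attr(expr_data, "truth"), file.path(out_dir, "true_network.tsv"))

  identified <- stage("identify", identify_network(nets$candidate, expr_data))
  write_network(identified, file.path(out_dir, "identified_network.tsv"))

  W <- stage("pnp", assemble_W(identified))
  proj <- stage("pnp", pnp(W, threshold = config$pnp_threshold,
                           K = config$core_size))
  core <- stage("pnp", extract_core(identified, proj))
  utils::write.table(
    transform(proj$ranking, Q = fmt_num(Q)),
    file.path(out_dir, "node_ranking.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  write_network(list(edges = core$edges), file.path(out_dir, "core_network.tsv"))
  jsonlite::write_json(
    list(singular_values = proj$singular_values,
         eigen_fractions = proj$eigen_fractions,
         X = proj$X, threshold = proj$threshold),
    file.path(out_dir, "projection_summary.json"),
    auto_unbox = TRUE, digits = NA)

  dti_data <- stage("dti", generate_dti_dataset(config$dti_data))
  dti <- stage("dti", run_dti(dti_data, config$training))
  jsonlite::write_json(
    list(test_accuracy = dti$test_accuracy, auc = dti$eval$auc,
         confusion = as.list(dti$eval$confusion)),
    file.path(out_dir, "dti_metrics.json"), auto_unbox = TRUE, digits = NA)

  fixture <- table1_fixture()
  combo <- stage("design", design_combination(fixture$drugs, fixture$targets,
                                              disease = config$disease,
                                              s_max = config$s_max))
  jsonlite::write_json(
    list(disease = combo$disease, drugs = combo$drugs,
         coverage = combo$coverage, trace = combo$trace),
    file.path(out_dir, "combination.json"), auto_unbox = TRUE, digits = NA)

  manifest <- list(
    package = "gwgenr",
    version = as.character(utils::packageVersion("gwgenr")),
    seed = config$seed,
    stages = c("simulate", "identify", "pnp", "dti", "design"),
    parameters = list(
      simulation = unclass(config$simulation),
      dti_data = unclass(config$dti_data),
      training = unclass(config$training),
      pnp_threshold = config$pnp_threshold,
      core_size = config$core_size,
      disease = config$disease,
      s_max = config$s_max
    ),
    outputs = list(
      identified_edges = nrow(identified$edges),
      candidate_edges = nrow(nets$candidate$edges),
      X = proj$X,
      dti_test_accuracy = dti$test_accuracy,
      dti_auc = dti$eval$auc,
      combination = combo$drugs
    )
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(networks = nets, expression = expr_data,
                 identified = identified, projection = proj, core = core,
                 dti = dti, combination = combo, manifest = manifest))
}
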