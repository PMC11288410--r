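# End-to-end orchestration: classify -> calibrate & bin -> similarity ->
# networks & metrics -> small-world -> bootstrap, with file outputs.

#' Pipeline configuration
#'
#' All defaults are the analysis settings of the reference study design:
#' 200-year bins over 8600-6801 cal BP, a 35% probability-mass binning
#' threshold, a 100-year date-error cutoff, Leiden/CPM at resolution
#' 0.02 with 1000 iterations and 100 restarts, and 1000 replicates for
#' both the small-world null ensemble and the bootstrap.
#'
#' @param bin_start,bin_end,bin_width Bin range and width (cal BP).
#' @param mass_threshold Minimum probability-mass fraction for bin
#'   membership.
#' @param mass_base `"two_sigma"` or `"full"` (see [assign_time_bins()]).
#' @param combine `"any"` or `"all"` across a context's dates.
#' @param sd_cutoff Maximum radiocarbon error (years).
#' @param leiden_resolution,leiden_iterations,leiden_restarts Leiden
#'   settings.
#' @param null_replicates Small-world null ensemble size.
#' @param bootstrap_replicates Bootstrap replicates.
#' @param seed Master seed for all stochastic stages.
#' @param normalise Apply the cross-bin diversity normalisation.
#' @param per_bin_filter Re-apply the shared-type filter within each bin.
#' @param weighted_metrics Compute topological metrics on weights.
#' @return A named list of class `run_config`.
#' @export
run_config <- function(bin_start = 8600, bin_end = 6801, bin_width = 200,
                       mass_threshold = 0.35, mass_base = "two_sigma",
                       combine = "any", sd_cutoff = 100,
                       leiden_resolution = 0.02, leiden_iterations = 1000,
                       leiden_restarts = 100, null_replicates = 1000,
                       bootstrap_replicates = 1000, seed = 42,
                       normalise = TRUE, per_bin_filter = FALSE,
                       weighted_metrics = FALSE) {
  structure(list(bin_start = bin_start, bin_end = bin_end,
                 bin_width = bin_width, mass_threshold = mass_threshold,
                 mass_base = mass_base, combine = combine,
                 sd_cutoff = sd_cutoff,
                 leiden_resolution = leiden_resolution,
                 leiden_iterations = leiden_iterations,
                 leiden_restarts = leiden_restarts,
                 null_replicates = null_replicates,
                 bootstrap_replicates = bootstrap_replicates,
                 seed = as.integer(seed), normalise = normalise,
                 per_bin_filter = per_bin_filter,
                 weighted_metrics = weighted_metrics),
            class = "run_config")
}

#' Minimal GEXF export of a similarity network
#'
#' Writes a static GEXF 1.3 file with node attributes (site, level,
#' community, betweenness, eigenvector, where present) and edge weights.
#'
#' @param g An undirected weighted graph.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_gexf <- function(g, path) {
  esc <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    x <- gsub(">", "&gt;", x, fixed = TRUE)
    gsub("\"", "&quot;", x, fixed = TRUE)
  }
  vattr <- setdiff(igraph::vertex_attr_names(g), "name")
  atype <- vapply(vattr, function(a) {
    if (is.numeric(igraph::vertex_attr(g, a))) "double" else "string"
  }, character(1L))
  lines <- c(
    "<?xml version=\"1.0\" encoding=\"UTF-8\"?>",
    "<gexf xmlns=\"http://gexf.net/1.3\" version=\"1.3\">",
    "  <graph defaultedgetype=\"undirected\" mode=\"static\">",
    "    <attributes class=\"node\">",
    sprintf("      <attribute id=\"%d\" title=\"%s\" type=\"%s\"/>",
            seq_along(vattr) - 1L, esc(vattr), atype),
    "    </attributes>",
    "    <nodes>")
  names_v <- igraph::V(g)$name
  if (is.null(names_v)) names_v <- as.character(seq_len(igraph::vcount(g)))
  for (i in seq_len(igraph::vcount(g))) {
    attrs <- vapply(seq_along(vattr), function(k) {
      val <- igraph::vertex_attr(g, vattr[k])[i]
      sprintf("        <attvalue for=\"%d\" value=\"%s\"/>", k - 1L,
              esc(as.character(val)))
    }, character(1L))
    lines <- c(lines,
               sprintf("      <node id=\"%s\" label=\"%s\">",
                       esc(names_v[i]), esc(names_v[i])),
               if (length(vattr)) c("        <attvalues>", attrs,
                                    "        </attvalues>"),
               "      </node>")
  }
  lines <- c(lines, "    </nodes>", "    <edges>")
  el <- igraph::as_edgelist(g)
  w <- if ("weight" %in% igraph::edge_attr_names(g)) igraph::E(g)$weight
       else rep(1, igraph::ecount(g))
  if (nrow(el) > 0L) {
    lines <- c(lines, sprintf(
      "      <edge id=\"%d\" source=\"%s\" target=\"%s\" weight=\"%g\"/>",
      seq_len(nrow(el)) - 1L, esc(el[, 1L]), esc(el[, 2L]), w))
  }
  lines <- c(lines, "    </edges>", "  </graph>", "</gexf>")
  writeLines(lines, path)
  invisible(path)
}

write_wide_matrix <- function(M, path) {
  df <- data.frame(context = rownames(M), M, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
}

#' Run the full similarity-network pipeline
#'
#' Executes every stage on the given input files and writes the output
#' bundle: the type inventory, per-context bin memberships, per-bin raw
#' and normalised similarity matrices (wide and long), the structural
#' metrics table, the node-turnover table, the small-world table, the
#' bootstrap summary, per-bin GraphML/GEXF exports, a run log and a
#' manifest echoing every setting and seed. Any stage error aborts with
#' the stage name.
#'
#' @param assemblage_path,dates_path,curve_path Input files (see
#'   [read_assemblage()], [read_c14_dates()], [read_cal_curve()]).
#' @param out_dir Output directory (created if needed).
#' @param config A [run_config()].
#' @return Invisibly, a list with all in-memory stage results
#'   (`inventory`, `kept`, `membership`, `assemblages`, `similarity`,
#'   `networks`, `metrics`, `ntr`, `smallworld`, `bootstrap`, `paths`).
#' @export
run_pipeline <- function(assemblage_path, dates_path, curve_path, out_dir,
                         config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  graph_dir <- file.path(out_dir, "graphs")
  if (!dir.exists(graph_dir)) dir.create(graph_dir)
  log_lines <- character(0)
  log <- function(fmt, ...) {
    line <- sprintf(fmt, ...)
    message(line)
    log_lines <<- c(log_lines, line)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }

  records <- stage("classify", read_assemblage(assemblage_path))
  inventory <- stage("classify", build_type_inventory(records))
  kept <- stage("classify", filter_shared_types(inventory, records))
  log("classify: %d records, %d types; %d records in %d shared types kept",
      nrow(records), nrow(inventory), nrow(kept$records), nrow(kept$types))

  curve <- stage("calibrate", read_cal_curve(curve_path))
  dates <- stage("calibrate", read_c14_dates(dates_path))
  dates <- stage("calibrate",
                 filter_c14_dates(dates, sd_cutoff = config$sd_cutoff))
  bins <- time_bins(config$bin_start, config$bin_end, config$bin_width)
  membership <- stage("bin", suppressWarnings(
    assign_time_bins(dates, curve, bins,
                     threshold = config$mass_threshold,
                     mass_base = config$mass_base,
                     combine = config$combine)))
  log("bin: %d contexts assigned across %d bins", nrow(membership),
      nrow(bins))

  assemblages <- list()
  for (b in bins$label) {
    a <- tryCatch(suppressWarnings(
      build_bin_assemblage(kept$records, membership, b,
                           per_bin_filter = config$per_bin_filter)),
      error = function(e) NULL)
    if (!is.null(a) && length(a$contexts) >= 2L) {
      assemblages[[b]] <- a
    } else {
      log("bin %s skipped: fewer than 2 populated contexts", b)
    }
  }
  if (length(assemblages) == 0L) {
    stop("pipeline stage 'similarity' failed: no bin has 2 or more contexts",
         call. = FALSE)
  }

  J_list <- stage("similarity",
                  lapply(assemblages, function(a) jaccard_matrix(a$binary)))
  n_types <- vapply(assemblages, `[[`, 0, "n_types")
  if (config$normalise) {
    norm <- stage("similarity", normalise_similarity(J_list, n_types))
  } else {
    norm <- list(J_norm = J_list,
                 scale_factor = stats::setNames(rep(1, length(J_list)),
                                                names(J_list)))
  }
  log("similarity: scale factors %s",
      paste(sprintf("%s=%.3f", names(norm$scale_factor),
                    norm$scale_factor), collapse = ", "))

  leiden_cfg <- list(resolution = config$leiden_resolution,
                     iterations = config$leiden_iterations,
                     restarts = config$leiden_restarts,
                     seed = config$seed)
  networks <- list(); metrics_rows <- list(); sw_rows <- list()
  boot_rows <- list(); node_sets <- list()
  sw_results <- list(); boot_reports <- list()
  for (b in names(assemblages)) {
    g <- stage("network", build_network(norm$J_norm[[b]], bin = b))
    met <- stage("network",
                 network_metrics(g, leiden = leiden_cfg,
                                 weighted = config$weighted_metrics))
    node_sets[[b]] <- assemblages[[b]]$contexts
    ctx <- igraph::V(g)$name
    parts <- strsplit(ctx, ":", fixed = TRUE)
    g <- igraph::set_vertex_attr(g, "site",
                                 value = vapply(parts, `[[`, "", 1L))
    g <- igraph::set_vertex_attr(g, "level",
                                 value = vapply(parts, function(p)
                                   paste(p[-1L], collapse = ":"), ""))
    g <- igraph::set_vertex_attr(g, "community",
                                 value = as.integer(met$membership[ctx]))
    g <- igraph::set_vertex_attr(g, "betweenness",
                                 value = unname(met$betweenness[ctx]))
    g <- igraph::set_vertex_attr(g, "eigenvector",
                                 value = unname(met$eigenvector[ctx]))
    networks[[b]] <- g
    igraph::write_graph(g, file.path(graph_dir, paste0("bin_", b, ".graphml")),
                        format = "graphml")
    write_gexf(g, file.path(graph_dir, paste0("bin_", b, ".gexf")))

    metrics_rows[[b]] <- data.frame(
      bin = b, n_nodes = met$n_nodes, n_edges = met$n_edges,
      density = met$density, clustering = met$clustering, apl = met$apl,
      n_communities = met$n_communities,
      leiden_quality = met$leiden_quality,
      scale_factor = unname(norm$scale_factor[b]),
      n_types = assemblages[[b]]$n_types,
      n_sample = assemblages[[b]]$n_sample,
      filter_applied = config$per_bin_filter,
      stringsAsFactors = FALSE)

    sw <- stage("smallworld",
                small_world_test(g, replicates = config$null_replicates,
                                 seed = config$seed))
    sw_results[[b]] <- sw
    sw_rows[[b]] <- data.frame(
      bin = b, observed_cc = sw$observed_cc,
      mean_null_cc = sw$mean_null_cc, observed_apl = sw$observed_apl,
      mean_null_apl = sw$mean_null_apl, sigma = sw$sigma,
      verdict = sw$verdict, stringsAsFactors = FALSE)

    br <- stage("bootstrap",
                bootstrap_bin(assemblages[[b]],
                              replicates = config$bootstrap_replicates,
                              seed = config$seed,
                              scale_factor = unname(norm$scale_factor[b])))
    boot_reports[[b]] <- br
    boot_rows[[b]] <- data.frame(bin = b, br$summary,
                                 stringsAsFactors = FALSE)
    log("network %s: %d nodes, %d edges, %d communities, sigma %.3f (%s)",
        b, met$n_nodes, met$n_edges, met$n_communities, sw$sigma,
        sw$verdict)
  }

  metrics <- do.call(rbind, metrics_rows); rownames(metrics) <- NULL
  swtab <- do.call(rbind, sw_rows); rownames(swtab) <- NULL
  boottab <- do.call(rbind, boot_rows); rownames(boottab) <- NULL
  turnover <- if (length(node_sets) >= 2L) ntr(node_sets) else NULL

  paths <- list(
    types = file.path(out_dir, "type_inventory.csv"),
    membership = file.path(out_dir, "bin_membership.csv"),
    similarity_long = file.path(out_dir, "similarity_long.csv"),
    metrics = file.path(out_dir, "network_metrics.csv"),
    ntr = file.path(out_dir, "node_turnover.csv"),
    smallworld = file.path(out_dir, "smallworld.csv"),
    bootstrap = file.path(out_dir, "bootstrap_summary.csv"),
    manifest = file.path(out_dir, "manifest.json"),
    log = file.path(out_dir, "run.log"))
  write_type_inventory(inventory, paths$types)
  utils::write.csv(membership, paths$membership, row.names = FALSE,
                   quote = FALSE)
  utils::write.csv(similarity_long(J_list, norm$J_norm),
                   paths$similarity_long, row.names = FALSE, quote = FALSE)
  for (b in names(J_list)) {
    write_wide_matrix(J_list[[b]],
                      file.path(out_dir, paste0("jaccard_", b, ".csv")))
    write_wide_matrix(norm$J_norm[[b]],
                      file.path(out_dir, paste0("jaccard_norm_", b, ".csv")))
  }
  utils::write.csv(metrics, paths$metrics, row.names = FALSE, quote = FALSE)
  if (!is.null(turnover)) {
    out_turn <- turnover
    out_turn$ntr <- round(out_turn$ntr, 3)
    utils::write.csv(out_turn, paths$ntr, row.names = FALSE, quote = FALSE)
  }
  utils::write.csv(swtab, paths$smallworld, row.names = FALSE, quote = FALSE)
  utils::write.csv(boottab, paths$bootstrap, row.names = FALSE,
                   quote = FALSE)
  manifest <- list(package = "lithnet",
                   version = as.character(utils::packageVersion("lithnet")),
                   inputs = list(assemblage = assemblage_path,
                                 dates = dates_path, curve = curve_path),
                   config = unclass(config),
                   bins = bins$label,
                   outputs = vapply(paths, basename, character(1L)))
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  writeLines(log_lines, paths$log)

  invisible(list(inventory = inventory, kept = kept,
                 membership = membership, bins = bins,
                 assemblages = assemblages,
                 similarity = list(J = J_list, J_norm = norm$J_norm,
                                   scale_factor = norm$scale_factor),
                 networks = networks, metrics = metrics, ntr = turnover,
                 smallworld = list(table = swtab, results = sw_results),
                 bootstrap = list(table = boottab, reports = boot_reports),
                 paths = paths))
}
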