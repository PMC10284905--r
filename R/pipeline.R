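.config_defaults <- function() list(
    tree = NULL, matrix = NULL, gene_sets = NULL, coordinates = NULL,
    out_dir = NULL, method = "fitch", present_min = 0.9, absent_max = 0.1,
    theta = 0.9, root_prior = "stationary", unit_lengths = FALSE,
    rate_bounds = c(1e-6, 1e3), tol = 1e-8, max_gap = 10000, seed = 1,
    log_level = "info")

#' Read a pipeline run configuration
#'
#' A flat YAML key-value document with the keys of the run configuration
#' (`tree`, `matrix`, `gene_sets`, `coordinates`, `out_dir`, `method`,
#' `present_min`, `absent_max`, `theta`, `root_prior`, `unit_lengths`,
#' `rate_bounds`, `tol`, `max_gap`, `seed`, `log_level`). Unset keys take
#' package defaults; `overrides` (e.g. from CLI flags) win over the file.
#' Every effective value, defaulted or not, is echoed into `summary.json`
#' by [runPipeline()] so no threshold is ever silent.
#'
#' @param path YAML file (or `NULL` to start from defaults only).
#' @param overrides named list of values overriding the file.
#' @return named list, validated.
#' @export
readRunConfig <- function(path = NULL, overrides = list()) {
    cfg <- .config_defaults()
    if (!is.null(path)) {
        if (!file.exists(path)) stop("config file not found: ", path)
        user <- yaml::read_yaml(path)
        unknown <- setdiff(names(user), names(cfg))
        if (length(unknown))
            stop("unknown config key(s): ", paste(unknown, collapse = ", "))
        cfg[names(user)] <- user
    }
    unknown <- setdiff(names(overrides), names(cfg))
    if (length(unknown))
        stop("unknown config key(s): ", paste(unknown, collapse = ", "))
    cfg[names(overrides)] <- overrides
    if (!cfg$method %in% c("fitch", "mk"))
        stop("method must be 'fitch' or 'mk'")
    if (!(cfg$absent_max >= 0 && cfg$absent_max < cfg$present_min &&
          cfg$present_min <= 1))
        stop("thresholds must satisfy 0 <= absent_max < present_min <= 1")
    if (cfg$theta <= 0 || cfg$theta > 1) stop("theta must be in (0, 1]")
    cfg
}

.log_line <- function(con, level, msg) {
    line <- paste0("[", level, "] ", msg)
    message(line)
    if (!is.null(con)) writeLines(line, con)
    invisible(NULL)
}

#' Run the full gene-set evolution pipeline
#'
#' Orchestrates: read tree + occurrence matrix + gene sets, reconcile
#' genomes with tips (extra genomes are dropped with a warning; tree tips
#' absent from the matrix are an error naming them), per-gene ancestral
#' reconstruction, set-level state profiles, consensus event calls, and
#' optional synteny clustering. Deterministic given the configuration.
#'
#' Writes to `out_dir`: `node_states.tsv`, `set_states.tsv`, `events.tsv`,
#' `events_genes.tsv`, `clusters.tsv` (when coordinates are given),
#' `annotated.nhx` (per-node set states as NHX annotations), `itol.tsv`
#' (plain per-node annotation export), `summary.json` (full config echo,
#' package version, per-set root state and event counts) and `run.log`.
#'
#' @param config a config list from [readRunConfig()], or a path to a YAML
#'   config file.
#' @param overrides named list overriding config values.
#' @return (invisibly) list with `nodeStates` (per set), `profiles`,
#'   `events`, `clusters`, `summary`.
#' @export
runPipeline <- function(config, overrides = list()) {
    if (is.null(config) || is.character(config))
        config <- readRunConfig(config, overrides)
    else if (length(overrides)) config[names(overrides)] <- overrides
    for (key in c("tree", "matrix", "gene_sets", "out_dir"))
        if (is.null(config[[key]])) stop("config key '", key, "' is required")
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    logcon <- file(file.path(config$out_dir, "run.log"), open = "wt")
    on.exit(close(logcon), add = TRUE)
    log <- function(...) .log_line(logcon, "info", paste0(...))

    tree <- parseNewick(file = config$tree)
    tm <- readTraitMatrix(config$matrix)
    catalog <- readGeneSetCatalog(config$gene_sets,
                                  presentMin = config$present_min,
                                  absentMax = config$absent_max)
    log("tree: ", ape::Ntip(tree), " tips; cladogram = ", isCladogram(tree))
    log("matrix: ", length(genomeIds(tm)), " genomes x ",
        length(geneIds(tm)), " genes")

    missing_tips <- setdiff(tree$tip.label, genomeIds(tm))
    if (length(missing_tips))
        stop("matrix is missing tree tip(s): ",
             paste(missing_tips, collapse = ", "))
    extra <- setdiff(genomeIds(tm), tree$tip.label)
    if (length(extra)) {
        warning("dropping ", length(extra),
                " genome(s) not on the tree: ",
                paste(extra, collapse = ", "))
        log("dropped off-tree genomes: ", paste(extra, collapse = ", "))
        tm <- tm[, tree$tip.label]
    }
    missing_genes <- setdiff(setMembership(catalog)$gene_id, geneIds(tm))
    if (length(missing_genes))
        stop("matrix is missing catalog gene(s): ",
             paste(missing_genes, collapse = ", "))

    if (config$method == "mk" && isCladogram(tree) && !config$unit_lengths)
        stop("method 'mk' on a cladogram requires unit_lengths = TRUE ",
             "(branch lengths are needed for the Mk model)")

    results <- list(); profiles <- list(); eventsets <- list()
    ns_tables <- list(); set_tables <- list()
    summary_sets <- list()
    root <- ape::Ntip(tree) + 1L
    for (s in setIds(catalog)) {
        genes <- setMembers(catalog, s)
        log("set '", s, "': ", length(genes), " genes, method = ",
            config$method)
        ns <- ancestralStates(tree, tm, genes = genes,
                              method = config$method,
                              rootPrior = config$root_prior,
                              unitLengths = config$unit_lengths,
                              bounds = as.numeric(config$rate_bounds),
                              tol = config$tol)
        prof <- setStates(ns, genes, set = s,
                          presentMin = config$present_min,
                          absentMax = config$absent_max)
        ec <- callEvents(ns, prof, theta = config$theta)
        results[[s]] <- ns; profiles[[s]] <- prof; eventsets[[s]] <- ec
        df <- as.data.frame(ns@states)
        ns_tables[[s]] <- data.frame(
            gene_id = df$gene_id, node_id = df$node_id,
            method = config$method, state_set = df$state_set,
            p0 = df$p0, p1 = df$p1, resolved_state = df$resolved)
        pf <- as.data.frame(setProfile(prof))
        set_tables[[s]] <- data.frame(set_name = s, pf)
        ce <- consensusEvents(ec)
        summary_sets[[s]] <- list(
            root_state = rootState(prof, tree),
            n_events = nrow(ce),
            n_unsupported = nrow(eventTable(ec)) - nrow(ce),
            events = as.data.frame(
                ce[, c("parent_id", "child_id", "event_type", "agreement")]))
        log("set '", s, "': root = ", rootState(prof, tree), ", ",
            nrow(ce), " consensus event(s)")
        for (r in seq_len(nrow(prof@profile)))
            tree <- annotateNode(tree, prof@profile$node[r],
                                 paste0("state_", gsub("[^A-Za-z0-9_]", "_", s)),
                                 prof@profile$state[r])
    }

    out <- function(f) file.path(config$out_dir, f)
    utils::write.table(do.call(rbind, ns_tables), out("node_states.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(do.call(rbind, set_tables), out("set_states.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    all_ev <- do.call(rbind, lapply(eventsets, function(e)
        as.data.frame(e@events)))
    all_gv <- do.call(rbind, lapply(eventsets, function(e)
        as.data.frame(e@genes)))
    utils::write.table(
        all_ev[, c("set_name", "parent_id", "child_id", "event_type",
                   "agreement", "supported")],
        out("events.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(all_gv, out("events_genes.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    writeNewick(tree, out("annotated.nhx"), annotations = TRUE)
    itol <- do.call(rbind, lapply(names(profiles), function(s) {
        pf <- as.data.frame(setProfile(profiles[[s]]))
        data.frame(node_id = pf$node_id, set_name = s,
                   fraction = pf$fraction, state = pf$state)
    }))
    utils::write.table(itol, out("itol.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)

    clusters <- NULL
    if (!is.null(config$coordinates)) {
        coords <- readCoordinates(config$coordinates)
        goi <- setMembership(catalog)$gene_id
        clusters <- findClusters(coords, goi, maxGap = config$max_gap)
        writeClusters(clusters, out("clusters.tsv"))
        log("synteny: ", nrow(clusters), " cluster(s) across ",
            length(unique(clusters$genome)), " genome(s)")
    }

    summary <- list(
        package = "gleam",
        version = as.character(utils::packageVersion("gleam")),
        config = config[order(names(config))],
        dropped_genomes = extra,
        sets = summary_sets)
    jsonlite::write_json(summary, out("summary.json"), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE, null = "null")
    log("done")
    invisible(list(nodeStates = results, profiles = profiles,
                   events = eventsets, clusters = clusters,
                   summary = summary, tree = tree))
}
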