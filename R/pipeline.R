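# End-to-end pipeline: configuration, output writers, and the run driver tying
# structure preparation, model building, network construction, TPT analysis
# and the dissociation-entropy scan together.

#' Assemble a run configuration
#'
#' @param pdb PDB file path (or PDB text); `NULL` to use a toy model instead.
#' @param chains two chain identifiers.
#' @param toy_template,toy_n_units used when `pdb` is `NULL`, see
#'   [toy_dimer()].
#' @param target_units,unit_size segmentation control, see
#'   [dimer_model_from_pdb()].
#' @param per_residue_entropy J/(K mol) per structured residue (default 16.5,
#'   a documented assumption).
#' @param secondary_structure DSSP file, secondary-structure string, or `NULL`.
#' @param temperature K (default 310).
#' @param s_diss J/(K mol) (default 87).
#' @param epsilon J/mol, or `"calibrate"` (native-dimer probability 0.5).
#' @param folded_chain mechanism classification switch.
#' @param scan_grid dissociation-entropy grid for the scan; `NULL` skips it.
#' @param export_network write the edge/node tables (default FALSE).
#' @param out_dir output directory.
#' @param seed RNG seed recorded with the run.
#' @return list of class `run_config`.
#' @export
run_config <- function(pdb = NULL, chains = c("A", "B"),
                       toy_template = "hairpin", toy_n_units = 3,
                       target_units = 12, unit_size = NULL,
                       per_residue_entropy = 16.5,
                       secondary_structure = NULL,
                       temperature = 310, s_diss = 87,
                       epsilon = "calibrate",
                       folded_chain = "contacts",
                       scan_grid = NULL, export_network = FALSE,
                       out_dir = ".", seed = 1) {
  stopifnot(temperature > 0, s_diss >= 0, per_residue_entropy >= 0)
  if (!identical(epsilon, "calibrate") &&
      (!is.numeric(epsilon) || epsilon <= 0))
    stop("epsilon must be a positive number or \"calibrate\"")
  structure(as.list(environment()), class = "run_config")
}

#' Read a plain-text key=value configuration file
#'
#' Lines are `key = value`; `#` starts a comment. Values are parsed as
#' numbers where possible; `scan_grid` accepts comma-separated values.
#' Unknown keys are an error. Explicit arguments in `...` override file
#' values.
#'
#' @param path configuration file.
#' @param ... overrides passed to [run_config()].
#' @return a [run_config()].
#' @export
read_run_config <- function(path, ...) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[nzchar(trimws(lines))])
  kv <- regmatches(lines, regexec("^([^=]+)=(.*)$", lines))
  args <- list()
  for (m in kv) {
    if (length(m) != 3L) stop("malformed config line: ", m[1L])
    key <- trimws(m[2L]); val <- trimws(m[3L])
    if (key == "chains") val <- trimws(strsplit(val, ",")[[1L]])
    else if (key == "scan_grid") val <- as.numeric(strsplit(val, ",")[[1L]])
    else if (!is.na(suppressWarnings(as.numeric(val)))) val <- as.numeric(val)
    else if (val %in% c("TRUE", "FALSE")) val <- as.logical(val)
    args[[key]] <- val
  }
  overrides <- list(...)
  args[names(overrides)] <- overrides
  bad <- setdiff(names(args), names(formals(run_config)))
  if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "))
  do.call(run_config, args)
}

# provenance header lines for the output files
.run_header <- function(config, extra = character(0)) {
  ver <- as.character(utils::packageVersion("dimerTPT"))
  chk <- if (!is.null(config$pdb) && length(config$pdb) == 1L &&
             !grepl("\n", config$pdb) && file.exists(config$pdb))
    as.character(tools::md5sum(config$pdb)) else NA_character_
  c(sprintf("# dimerTPT %s", ver),
    sprintf("# temperature=%g s_diss=%g epsilon=%s per_residue_entropy=%g seed=%s",
            config$temperature, config$s_diss,
            if (identical(config$epsilon, "calibrate")) "calibrate"
            else format(config$epsilon),
            config$per_residue_entropy, format(config$seed)),
    sprintf("# input=%s md5=%s",
            if (is.null(config$pdb)) sprintf("toy:%s:n=%d", config$toy_template,
                                             config$toy_n_units)
            else config$pdb[1L], chk),
    extra)
}

.write_csv_with_header <- function(df, path, header) {
  con <- file(path, "w")
  writeLines(header, con)
  write.table(df, con, sep = ",", quote = FALSE, row.names = FALSE)
  close(con)
}

#' Run the full dimer-formation pipeline
#'
#' Builds the model (from a PDB structure or a toy template), calibrates
#' epsilon if requested, runs the TPT analysis, optionally scans the
#' dissociation entropy, and writes the output bundle to `config$out_dir`:
#' `model_summary.json`, `mechanisms.json`, `qmap.csv`, `foldedness.csv`,
#' plus `scan.csv` and `network_edges.tsv` / `network_nodes.tsv` on request.
#' Every file carries a provenance header (tool version, parameters, input
#' checksum).
#'
#' @param config a [run_config()].
#' @param quiet suppress progress messages.
#' @return invisibly, a list with the `dimer_tpt` result, the model, the scan
#'   (if any) and the written file paths.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  say <- function(...) if (!quiet) message(sprintf(...))
  stage <- "model building"
  res <- tryCatch({
    set.seed(config$seed)
    if (is.null(config$pdb)) {
      model <- toy_dimer(n_units = config$toy_n_units,
                         template = config$toy_template,
                         epsilon = if (identical(config$epsilon, "calibrate")) 1
                         else config$epsilon,
                         temperature = config$temperature,
                         s_diss = config$s_diss, seed = config$seed)
      if (identical(config$epsilon, "calibrate")) {
        model$epsilon <- calibrate_epsilon(model)
        attr(model, "calibrated") <- model$epsilon
      }
    } else {
      model <- dimer_model_from_pdb(
        config$pdb, config$chains, target_units = config$target_units,
        unit_size = config$unit_size,
        per_residue_entropy = config$per_residue_entropy,
        secondary_structure = config$secondary_structure,
        epsilon = config$epsilon, temperature = config$temperature,
        s_diss = config$s_diss)
    }
    say("model: %d units/chain, epsilon = %.1f J/mol",
        model$chain_A$n_units, model$epsilon)

    stage <- "TPT analysis"
    fit <- dimer_kinetics(model, folded_chain = config$folded_chain)
    say("network: %d nodes; f_total = %.4g; committor residual %.1e",
        fit$network$n_nodes, fit$f_total, fit$checks$committor_residual)

    stage <- "output writing"
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    hdr <- .run_header(config)
    paths <- list()

    ms <- model_summary(model)
    ms$calibrated_epsilon <- attr(model, "calibrated")
    ms$n_network_nodes_built <- fit$network$n_nodes
    ms$provenance <- hdr
    paths$model_summary <- file.path(config$out_dir, "model_summary.json")
    jsonlite::write_json(ms, paths$model_summary, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)

    mech <- list(provenance = hdr,
                 epsilon = model$epsilon,
                 calibrated = !is.null(attr(model, "calibrated")),
                 temperature = model$temperature, s_diss = fit$s_diss,
                 folded_chain = fit$folded_chain,
                 f_total = fit$f_total,
                 p_induced = fit$mechanism[["induced"]],
                 p_confsel = fit$mechanism[["confsel"]],
                 p_rigid = fit$mechanism[["rigid"]],
                 checks = fit$checks)
    paths$mechanisms <- file.path(config$out_dir, "mechanisms.json")
    jsonlite::write_json(mech, paths$mechanisms, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)

    n <- model$chain_A$n_units
    qdf <- data.frame(Q_A = 0:n, fit$q_map, check.names = FALSE)
    names(qdf) <- c("Q_A", paste0("QB_", 0:n))
    paths$qmap <- file.path(config$out_dir, "qmap.csv")
    .write_csv_with_header(qdf, paths$qmap, hdr)

    fu <- fit$foldedness
    unit_df <- data.frame(granularity = "unit",
                          chain = rep(c("A", "B"), each = n),
                          index = rep(seq_len(n), 2L),
                          foldedness = c(fu$unit_A, fu$unit_B))
    res_df <- data.frame(granularity = "residue",
                         chain = rep(c("A", "B"),
                                     c(length(fu$residue_A), length(fu$residue_B))),
                         index = c(seq_along(fu$residue_A), seq_along(fu$residue_B)),
                         foldedness = c(fu$residue_A, fu$residue_B))
    paths$foldedness <- file.path(config$out_dir, "foldedness.csv")
    .write_csv_with_header(rbind(unit_df, res_df), paths$foldedness, hdr)

    scan <- NULL
    if (!is.null(config$scan_grid)) {
      stage <- "dissociation-entropy scan"
      scan <- sdiss_scan(model, config$scan_grid,
                         folded_chain = config$folded_chain)
      paths$scan <- file.path(config$out_dir, "scan.csv")
      .write_csv_with_header(scan$table, paths$scan, hdr)
    }
    if (isTRUE(config$export_network)) {
      stage <- "network export"
      paths$network_edges <- file.path(config$out_dir, "network_edges.tsv")
      paths$network_nodes <- file.path(config$out_dir, "network_nodes.tsv")
      export_network(fit$network, paths$network_edges, paths$network_nodes,
                     header_lines = hdr)
    }
    list(fit = fit, model = model, scan = scan, paths = paths)
  }, error = function(e) {
    stop(sprintf("pipeline failed during %s: %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
  invisible(res)
}
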