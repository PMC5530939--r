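#' Run the full inference-and-evaluation pipeline
#'
#' Reads the three inputs, prunes the reference to gene-annotated terms
#' (reconnecting ancestry), infers a disease tree with each requested
#' method over the pruned term set, evaluates every inferred tree against
#' the pruned reference, and writes per-method edge lists plus a combined
#' report TSV to `out_dir`. Any component error aborts before the report is
#' written.
#'
#' @param associations path to an association TSV (`disease_id<TAB>gene_id`).
#' @param citations path to a citation TSV (`disease_id<TAB>count`).
#' @param reference path to the reference hierarchy.
#' @param out_dir output directory (created if needed).
#' @param ref_format `"edges"` (edge-list TSV), `"obo"`, or `"mesh"`
#'   (tree-number TSV).
#' @param methods inference methods to run.
#' @param seed recorded in output headers for provenance (the pipeline
#'   itself is deterministic).
#' @param quiet suppress progress messages.
#' @return invisibly, a list with the pruned `reference`, the inferred
#'   `trees`, and the `report` data frame (one row per method with columns
#'   method, ec, ac, ap, ar, f, n_shared_terms, n_ref_edges).
#' @export
run_pipeline <- function(associations, citations, reference, out_dir,
                         ref_format = c("edges", "obo", "mesh"),
                         methods = c("parent_promotion", "mwst"),
                         seed = NULL, quiet = FALSE) {
  ref_format <- match.arg(ref_format)
  for (p in c(associations, citations, reference)) {
    if (!file.exists(p)) stop(sprintf("input file not found: %s", p),
                              call. = FALSE)
  }
  table <- read_associations(associations, quiet = quiet)
  cites <- read_citations(citations)
  ref <- switch(ref_format,
                edges = read_hierarchy(reference),
                obo = read_obo(reference),
                mesh = read_mesh_trees(reference))
  pruned <- prune_and_reconnect(ref, table, quiet = quiet)
  diseases <- lex_sort(pruned$nodes$id)
  if (length(diseases) < 2L) {
    stop("fewer than two reference terms have gene annotations", call. = FALSE)
  }
  trees <- list()
  rows <- list()
  for (m in methods) {
    tree <- infer(m, table, diseases, cites, quiet = quiet)
    rep <- evaluate_hierarchy(pruned, tree, quiet = quiet)
    trees[[m]] <- tree
    rows[[m]] <- data.frame(method = m, ec = rep$ec, ac = rep$ac,
                            ap = rep$ap, ar = rep$ar, f = rep$f,
                            n_shared_terms = rep$n_shared_terms,
                            n_ref_edges = rep$n_ref_edges,
                            stringsAsFactors = FALSE)
    if (!quiet) {
      message(sprintf("%s: EC %.3f AC %.3f AP %.3f AR %.3f F %.3f",
                      m, rep$ec, rep$ac, rep$ap, rep$ar, rep$f))
    }
  }
  report <- do.call(rbind, rows)
  rownames(report) <- NULL
  # all computations succeeded; only now touch the output directory
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  meta <- c(sprintf("diseasetree %s",
                    as.character(utils::packageVersion("diseasetree"))),
            if (!is.null(seed)) sprintf("seed=%s", seed))
  for (m in names(trees)) {
    write_hierarchy(trees[[m]],
                    file.path(out_dir, paste0(m, "_edges.tsv")),
                    comments = meta)
  }
  report_path <- file.path(out_dir, "report.tsv")
  lines <- c(paste0("#", meta),
             paste(names(report), collapse = "\t"),
             do.call(paste, c(lapply(report, as.character), sep = "\t")))
  writeLines(lines, report_path)
  invisible(list(reference = pruned, trees = trees, report = report))
}

# ---- command-line interface ------------------------------------------------
# exec/diseasetree forwards commandArgs(TRUE) here; returns an exit status.

cli_usage <- function() {
  paste(
    "usage: diseasetree <subcommand> [options]",
    "",
    "subcommands:",
    "  simulate  --n <terms> --seed <int> --out-dir <dir> [--noise <rate>]",
    "  infer     --method {pp|mwst} --associations <tsv> --citations <tsv>",
    "            --out <edges.tsv> [--diseases <id,id,...>]",
    "  evaluate  --ref <edges.tsv> --inf <edges.tsv> --out <report.tsv>",
    "  pipeline  --associations <tsv> --citations <tsv> --ref <file>",
    "            --ref-format {edges|obo|mesh} --out-dir <dir> [--seed <int>]",
    sep = "\n")
}

cli_opt <- function(args, flag, default = NULL, required = FALSE) {
  i <- which(args == flag)
  if (!length(i)) {
    if (required) stop(sprintf("missing required option %s", flag), call. = FALSE)
    return(default)
  }
  if (i[1L] + 1L > length(args)) {
    stop(sprintf("option %s needs a value", flag), call. = FALSE)
  }
  args[i[1L] + 1L]
}

cli_main <- function(args) {
  status <- tryCatch({
    if (!length(args) || args[1L] %in% c("-h", "--help")) {
      cat(cli_usage(), "\n")
      return(0L)
    }
    sub <- args[1L]
    rest <- args[-1L]
    switch(sub,
      simulate = {
        config <- synthetic_config(
          n_terms = as.integer(cli_opt(rest, "--n", required = TRUE)),
          noise_swap_rate = as.numeric(cli_opt(rest, "--noise", "0")),
          seed = as.integer(cli_opt(rest, "--seed", "1")))
        write_synthetic_dataset(config,
                                cli_opt(rest, "--out-dir", required = TRUE))
      },
      infer = {
        method <- cli_opt(rest, "--method", required = TRUE)
        table <- read_associations(cli_opt(rest, "--associations",
                                           required = TRUE))
        cites <- read_citations(cli_opt(rest, "--citations", required = TRUE))
        spec <- cli_opt(rest, "--diseases")
        diseases <- if (is.null(spec)) lex_sort(unique(table$disease_id))
                    else strsplit(spec, ",", fixed = TRUE)[[1L]]
        tree <- infer(method, table, diseases, cites)
        write_hierarchy(tree, cli_opt(rest, "--out", required = TRUE))
      },
      evaluate = {
        ref <- read_hierarchy(cli_opt(rest, "--ref", required = TRUE))
        inf <- read_hierarchy(cli_opt(rest, "--inf", required = TRUE))
        rep <- evaluate_hierarchy(ref, inf)
        out <- cli_opt(rest, "--out", required = TRUE)
        writeLines(c("ec\tac\tap\tar\tf\tn_shared_terms\tn_ref_edges",
                     paste(rep$ec, rep$ac, rep$ap, rep$ar, rep$f,
                           rep$n_shared_terms, rep$n_ref_edges, sep = "\t")),
                   out)
      },
      pipeline = {
        run_pipeline(
          associations = cli_opt(rest, "--associations", required = TRUE),
          citations = cli_opt(rest, "--citations", required = TRUE),
          reference = cli_opt(rest, "--ref", required = TRUE),
          out_dir = cli_opt(rest, "--out-dir", required = TRUE),
          ref_format = cli_opt(rest, "--ref-format", "edges"),
          seed = cli_opt(rest, "--seed"))
      },
      stop(sprintf("unknown subcommand '%s'\n%s", sub, cli_usage()),
           call. = FALSE))
    0L
  }, error = function(e) {
    message(conditionMessage(e))
    1L
  })
  status
}
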