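`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a study configuration
#'
#' YAML (or JSON) file describing one full analysis: backbone tree path,
#' ordered `sources` list (each `tree` + `landmark`), `ranges` and
#' `evidence` paths, named `clades` (clade -> defining taxon set, >= 2
#' taxa), and the knobs `mbl`, `tip_age_policy`, `min_ribs`, `root_prior`,
#' `mcmc` (iterations, burn_in_fraction, thin) and `seed`. Relative paths
#' are resolved against the config file's directory.
#'
#' @param file path to the YAML/JSON config.
#' @return a validated `study_config` list.
#' @export
read_study_config <- function(file) {
  if (!file.exists(file)) stop("config file not found: ", file)
  cfg <- if (grepl("\\.json$", file, ignore.case = TRUE))
    jsonlite::read_json(file, simplifyVector = TRUE)
  else yaml::read_yaml(file)
  base <- dirname(normalizePath(file))
  resolve <- function(p) {
    if (is.null(p)) return(NULL)
    if (file.exists(p)) p else file.path(base, p)
  }
  cfg$backbone <- resolve(cfg$backbone)
  cfg$ranges <- resolve(cfg$ranges)
  cfg$evidence <- resolve(cfg$evidence)
  cfg$sources <- lapply(cfg$sources, function(s) {
    s$tree <- resolve(s$tree)
    s
  })
  validate_study_config(cfg)
}

#' Validate a study configuration list
#'
#' @param cfg a list as produced by [read_study_config()] (tree entries may
#'   also be in-memory `phylo` objects and `sources[[i]]$tree` likewise).
#' @return the config with defaults filled in, classed `study_config`.
#' @export
validate_study_config <- function(cfg) {
  for (f in c("backbone", "ranges", "evidence")) {
    v <- cfg[[f]]
    if (is.character(v) && !file.exists(v))
      stop("config ", f, " file not found: ", v)
  }
  for (s in cfg$sources) {
    if (is.null(s$landmark)) stop("every source needs a 'landmark'")
    if (is.character(s$tree) && !file.exists(s$tree))
      stop("source tree file not found: ", s$tree)
  }
  if (is.null(cfg$clades) || !length(cfg$clades))
    stop("config must define at least one clade")
  bad <- names(cfg$clades)[vapply(cfg$clades, length, integer(1L)) < 2L]
  if (length(bad))
    stop("clade(s) need >= 2 defining taxa: ", paste(bad, collapse = ", "))
  cfg$mbl <- cfg$mbl %||% 1
  cfg$tip_age_policy <- cfg$tip_age_policy %||% "FAD"
  cfg$min_ribs <- cfg$min_ribs %||% 5L
  cfg$root_prior <- cfg$root_prior %||% "flat"
  cfg$mcmc <- utils::modifyList(
    list(iterations = 100000L, burn_in_fraction = 0.2, thin = 50L),
    cfg$mcmc %||% list())
  cfg$seed <- cfg$seed %||% 1L
  structure(cfg, class = "study_config")
}

.as_tree <- function(x) if (inherits(x, "phylo")) x else read_newick(file = x)

#' Assemble the supertree from a backbone and ordered source trees
#'
#' Grafts each source onto the growing composite at its landmark, in the
#' order given (the order is user-supplied configuration: the grafting
#' protocol does not itself resolve conflicts among sources). Per-graft
#' tip counts are reported via `message()`; any graft error aborts with
#' the offending source named.
#'
#' @param config a `study_config`, or a list with `backbone` and `sources`.
#' @param quiet suppress per-graft messages.
#' @return the assembled `phylo`.
#' @export
assemble_supertree <- function(config, quiet = FALSE) {
  tree <- .as_tree(config$backbone)
  for (i in seq_along(config$sources)) {
    s <- config$sources[[i]]
    src <- .as_tree(s$tree)
    before <- length(tree$tip.label)
    tree <- tryCatch(
      graft(tree, src, s$landmark),
      error = function(e) stop("graft of source ", i, " (landmark '",
                               s$landmark, "') failed: ",
                               conditionMessage(e), call. = FALSE))
    if (!quiet)
      message("graft ", i, ": +", length(tree$tip.label) - before,
              " taxa at '", s$landmark, "' (", length(tree$tip.label),
              " tips)")
  }
  tree
}

#' Clade-level state summary from a reconstruction
#'
#' Looks up the most recent common ancestor of the clade's defining taxa
#' and returns its state summary: the probability vector (ML/Bayesian) or
#' MPR state set (parsimony) plus the best state. Probability ties within
#' `1e-6` are reported as ties (states joined with `/`), not broken.
#'
#' @param result an `asr_result`.
#' @param tree the tree the reconstruction was computed on.
#' @param clade_taxa character vector (>= 1) of defining taxa.
#' @param clade_name optional clade label carried into the output.
#' @return list with `clade`, `node`, `best_state` and either `prob`
#'   (named numeric) or `mpr` (integer states).
#' @export
extract_clade_probability <- function(result, tree, clade_taxa,
                                      clade_name = NULL) {
  node <- mrca_node(tree, clade_taxa)
  if (result$method == "MP") {
    mpr <- result$mpr[[node]]
    list(clade = clade_name, node = node,
         best_state = paste(mpr, collapse = "/"), mpr = mpr)
  } else {
    p <- result$prob[node, ]
    best <- STATES[p >= max(p) - 1e-6]
    list(clade = clade_name, node = node,
         best_state = paste(best, collapse = "/"),
         prob = setNames(as.numeric(p), paste0("state", STATES)))
  }
}

.grid_row <- function(coding, method, bl_mode, clade, summ, note = "") {
  if (!is.null(summ$prob)) {
    data.frame(coding = coding, method = method, bl_mode = bl_mode,
               clade = clade, best_state = summ$best_state,
               p0 = summ$prob[1L], p1 = summ$prob[2L], p2 = summ$prob[3L],
               mpr = "", note = note, stringsAsFactors = FALSE)
  } else {
    data.frame(coding = coding, method = method, bl_mode = bl_mode,
               clade = clade, best_state = summ$best_state,
               p0 = NA_real_, p1 = NA_real_, p2 = NA_real_,
               mpr = format_state_set(summ$mpr), note = note,
               stringsAsFactors = FALSE)
  }
}

#' Run the full analysis grid
#'
#' Executes the study design: {preferred, alternate} coding x {MP, ML, MB}
#' x {timescaled, unit} branch lengths, and summarizes every configured
#' clade in every cell. Parsimony ignores branch lengths, so each MP
#' analysis is run once per coding and its rows are repeated across both
#' branch-length modes with an explanatory note. A failed cell is recorded
#' (status `failed`, message in `note`) without aborting the others.
#' Bayesian cells derive their seeds deterministically from `config$seed`,
#' so rerunning with the same config reproduces identical reports.
#'
#' @param config a `study_config` (see [read_study_config()] /
#'   [validate_study_config()]).
#' @param quiet suppress progress messages.
#' @return a `grid_report`: list with `rows` (data.frame), `results`
#'   (named list of `asr_result`s), `tree` (the supertree), `config` echo
#'   and `versions`.
#' @export
run_grid <- function(config, quiet = FALSE) {
  config <- validate_study_config(unclass(config))
  supertree <- assemble_supertree(config, quiet = quiet)
  missing_cl <- unlist(lapply(config$clades, setdiff,
                              y = supertree$tip.label))
  if (length(missing_cl))
    stop("clade defining taxa absent from supertree: ",
         paste(unique(missing_cl), collapse = ", "))
  ranges <- if (is.character(config$ranges)) read_strat_ranges(config$ranges)
            else validate_strat_ranges(config$ranges)
  evidence <- if (is.character(config$evidence)) read_evidence(config$evidence)
              else validate_evidence(config$evidence)
  codings <- list(preferred = code_preferred(evidence),
                  alternate = code_alternate(evidence,
                                             min_ribs = config$min_ribs))
  trees <- list(
    timescaled = timescale_tree(supertree, ranges, mbl = config$mbl,
                                tip_age_policy = config$tip_age_policy),
    unit = unit_branch_lengths(supertree))

  rows <- list()
  results <- list()
  cell_i <- 0L
  for (cd in names(codings)) {
    mp <- tryCatch(sankoff_asr(supertree, codings[[cd]]),
                   error = function(e) e)
    for (bl in names(trees)) {
      tr <- trees[[bl]]
      cell_i <- cell_i + 1L

      # MP: identical across branch-length modes by construction
      key <- paste(cd, "MP", bl, sep = ".")
      if (inherits(mp, "error")) {
        rows[[key]] <- .grid_row(cd, "MP", bl, "*", list(
          best_state = "", mpr = integer()),
          note = paste("failed:", conditionMessage(mp)))
      } else {
        results[[key]] <- mp
        rows[[key]] <- do.call(rbind, lapply(names(config$clades), function(cn)
          .grid_row(cd, "MP", bl, cn,
                    extract_clade_probability(mp, supertree,
                                              config$clades[[cn]], cn),
                    note = "branch-length invariant")))
      }

      # ML: fit the rate, then exact marginals
      key <- paste(cd, "ML", bl, sep = ".")
      ml <- tryCatch({
        fit <- fit_mk(tr, codings[[cd]], root_prior = config$root_prior)
        marginal_asr_ml(tr, codings[[cd]], fit$model)
      }, error = function(e) e)
      if (inherits(ml, "error")) {
        rows[[key]] <- .grid_row(cd, "ML", bl, "*", list(
          best_state = "", mpr = integer()),
          note = paste("failed:", conditionMessage(ml)))
      } else {
        results[[key]] <- ml
        rows[[key]] <- do.call(rbind, lapply(names(config$clades), function(cn)
          .grid_row(cd, "ML", bl, cn,
                    extract_clade_probability(ml, tr,
                                              config$clades[[cn]], cn))))
      }

      # MB: seed derived from config seed and cell position
      key <- paste(cd, "MB", bl, sep = ".")
      mb <- tryCatch(suppressWarnings(bayes_asr(
        tr, codings[[cd]], seed = as.integer(config$seed) + 1000L * cell_i,
        iterations = config$mcmc$iterations,
        burn_in_fraction = config$mcmc$burn_in_fraction,
        thin = config$mcmc$thin, root_prior = config$root_prior)),
        error = function(e) e)
      if (inherits(mb, "error")) {
        rows[[key]] <- .grid_row(cd, "MB", bl, "*", list(
          best_state = "", mpr = integer()),
          note = paste("failed:", conditionMessage(mb)))
      } else {
        results[[key]] <- mb
        rows[[key]] <- do.call(rbind, lapply(names(config$clades), function(cn)
          .grid_row(cd, "MB", bl, cn,
                    extract_clade_probability(mb, tr,
                                              config$clades[[cn]], cn))))
      }
      if (!quiet) message("cells done: ", cd, " / ", bl)
    }
  }
  rows <- do.call(rbind, rows)
  rownames(rows) <- NULL
  structure(list(rows = rows, results = results, tree = supertree,
                 config = config,
                 versions = list(
                   paleoasr = as.character(packageVersion("paleoasr")),
                   ape = as.character(packageVersion("ape")),
                   R = paste(R.version$major, R.version$minor, sep = "."))),
            class = "grid_report")
}

#' @export
print.grid_report <- function(x, digits = 2, ...) {
  cat("analysis grid: 2 codings x {MP, ML, MB} x {timescaled, unit}\n")
  df <- x$rows
  for (col in c("p0", "p1", "p2"))
    df[[col]] <- ifelse(is.na(df[[col]]), "",
                        formatC(df[[col]], digits = digits, format = "f"))
  print(df, row.names = FALSE)
  invisible(x)
}

#' Write a grid report as TSV and JSON
#'
#' The TSV holds the per-clade rows; the JSON adds full-precision
#' probabilities and a provenance block (config echo, versions, seed).
#' Output is deterministic for a fixed config and seed.
#'
#' @param report a `grid_report`.
#' @param tsv,json output paths (either may be `NULL` to skip).
#' @export
write_grid_report <- function(report, tsv = NULL, json = NULL) {
  if (!is.null(tsv))
    write.table(report$rows, tsv, sep = "\t", quote = FALSE,
                row.names = FALSE)
  if (!is.null(json)) {
    cfg <- unclass(report$config)
    cfg$sources <- lapply(cfg$sources, function(s)
      list(tree = if (is.character(s$tree)) s$tree else "<in-memory>",
           landmark = s$landmark))
    for (f in c("backbone", "ranges", "evidence"))
      if (!is.character(cfg[[f]])) cfg[[f]] <- "<in-memory>"
    payload <- list(rows = report$rows,
                    provenance = list(config = cfg,
                                      versions = report$versions,
                                      seed = report$config$seed))
    jsonlite::write_json(payload, json, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  invisible(report)
}
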