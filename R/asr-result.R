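new_asr_result <- function(method, tree, ...) {
  structure(list(method = method, ntip = length(tree$tip.label),
                 nnode = tree$Nnode, bl_mode = tree$bl_mode, ...),
            class = "asr_result")
}

#' @export
print.asr_result <- function(x, ...) {
  cat("ancestral state reconstruction (", x$method, ")\n", sep = "")
  cat("  tree: ", x$ntip, " tips, ", x$nnode, " internal nodes",
      if (!is.null(x$bl_mode)) paste0(" [", x$bl_mode, " branch lengths]"),
      "\n", sep = "")
  if (x$method == "MP") {
    cat("  minimum changes:", x$cost, "\n")
  } else {
    if (!is.null(x$model))
      cat("  model: Mk-", x$model$parameterization, ", rate(s) ",
          paste(signif(x$model$rates, 4), collapse = ", "),
          " /Myr, logLik ", signif(x$loglik, 6), "\n", sep = "")
    if (!is.null(x$diagnostics))
      cat("  MCMC: ", x$diagnostics$n_retained, " retained samples, ",
          "acceptance ", round(x$diagnostics$acceptance, 3),
          ", rate ESS ", round(x$diagnostics$ess, 1),
          if (isTRUE(x$diagnostics$low_ess_flag)) " [LOW ESS]", "\n",
          sep = "")
  }
  invisible(x)
}

#' Per-node state summary of a reconstruction
#'
#' @param object an `asr_result`.
#' @param ... unused.
#' @return data.frame with one row per node: probabilities (ML/Bayesian) or
#'   MPR state set (parsimony).
#' @export
summary.asr_result <- function(object, ...) {
  nn <- object$ntip + object$nnode
  if (object$method == "MP") {
    data.frame(node = seq_len(nn),
               mpr = vapply(object$mpr, format_state_set, character(1L)))
  } else {
    p <- object$prob
    data.frame(node = seq_len(nn), p0 = p[, 1L], p1 = p[, 2L], p2 = p[, 3L])
  }
}

#' Export a reconstruction as JSON or TSV
#'
#' @param result an `asr_result`.
#' @param file output path; format chosen by extension (`.json` or
#'   anything else for TSV).
#' @export
write_asr_result <- function(result, file) {
  df <- summary.asr_result(result)
  if (grepl("\\.json$", file, ignore.case = TRUE)) {
    payload <- list(method = result$method, bl_mode = result$bl_mode,
                    nodes = df)
    jsonlite::write_json(payload, file, auto_unbox = TRUE, digits = NA)
  } else {
    write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(file)
}
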