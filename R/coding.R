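PROCESS_CLASSES <- c("none", "cartilaginous", "calcified", "ossified")

#' Default mapping from preserved-process class to character state
#'
#' The character has three states: 0 = uncinate process absent,
#' 1 = cartilaginous uncinate process, 2 = ossified uncinate process.
#' Calcified processes (e.g. ornithischian intercostal plates) are grouped
#' with the cartilaginous grade by default; the mapping is a plain named
#' vector and can be overridden per analysis.
#'
#' @return named integer vector over the process classes (`none` is `NA`:
#'   no positive evidence).
#' @export
default_process_map <- function() {
  c(none = NA_integer_, cartilaginous = 1L, calcified = 1L, ossified = 2L)
}

#' Read a specimen-evidence table
#'
#' Delimited text (TSV or CSV by extension) with header
#' `taxon, n_ribs_examined, n_ribs_with_scar, preserved_process,
#' override_state`. `preserved_process` is one of none, cartilaginous,
#' calcified, ossified; `override_state` is empty or a state set such as
#' `"0"`, `"1/2"`, `"?"`. Multiple rows per taxon are allowed (one per
#' specimen) and are aggregated downstream.
#'
#' @param file path.
#' @return a validated `data.frame`.
#' @export
read_evidence <- function(file) {
  if (!file.exists(file)) stop("evidence file not found: ", file)
  sep <- if (grepl("\\.csv$", file, ignore.case = TRUE)) "," else "\t"
  df <- read.delim(file, sep = sep, stringsAsFactors = FALSE,
                   colClasses = list(override_state = "character"))
  validate_evidence(df)
}

#' Validate a specimen-evidence table
#'
#' @param df data.frame; `override_state` column is optional.
#' @return the validated data.frame with canonical column types.
#' @export
validate_evidence <- function(df) {
  need <- c("taxon", "n_ribs_examined", "n_ribs_with_scar", "preserved_process")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("evidence table lacks column(s): ", paste(miss, collapse = ", "))
  if (!"override_state" %in% names(df)) df$override_state <- ""
  df$taxon <- as.character(df$taxon)
  df$override_state <- as.character(df$override_state)
  df$override_state[is.na(df$override_state)] <- ""
  df$preserved_process <- tolower(as.character(df$preserved_process))
  bad <- setdiff(unique(df$preserved_process), PROCESS_CLASSES)
  if (length(bad))
    stop("unknown preserved-process class(es): ", paste(bad, collapse = ", "))
  if (any(df$n_ribs_with_scar < 0 | df$n_ribs_examined < 0))
    stop("negative rib counts")
  over <- df$taxon[df$n_ribs_with_scar > df$n_ribs_examined]
  if (length(over))
    stop("more scarred ribs than ribs examined for: ",
         paste(over, collapse = ", "))
  df
}

# "0/1/2", "?", "{0,1}" -> sorted integer state set
parse_state_set <- function(s) {
  s <- trimws(s)
  if (!nzchar(s)) return(NULL)
  if (s == "?") return(STATES)
  parts <- strsplit(gsub("[{}() ]", "", s), "[/,]")[[1L]]
  v <- suppressWarnings(as.integer(parts))
  if (anyNA(v) || !all(v %in% STATES))
    stop("cannot parse state set: '", s, "'")
  sort(unique(v))
}

format_state_set <- function(v) {
  if (length(v) == length(STATES)) "?" else paste(v, collapse = "/")
}

# one row per taxon: counts summed, strongest process class kept,
# first non-empty override kept ("at least one specimen" semantics)
aggregate_evidence <- function(df) {
  df <- validate_evidence(df)
  if (nrow(df) == 0L) stop("empty evidence table")
  rank <- match(df$preserved_process, PROCESS_CLASSES)
  split_idx <- split(seq_len(nrow(df)), df$taxon)
  rows <- lapply(split_idx, function(i) {
    ov <- df$override_state[i][nzchar(df$override_state[i])]
    data.frame(
      taxon = df$taxon[i[1L]],
      n_ribs_examined = sum(df$n_ribs_examined[i]),
      n_ribs_with_scar = sum(df$n_ribs_with_scar[i]),
      preserved_process = PROCESS_CLASSES[max(rank[i])],
      override_state = if (length(ov)) ov[1L] else "",
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(match(out$taxon, df$taxon)), , drop = FALSE]
}

#' State implied by one taxon's aggregated evidence
#'
#' Returns the single state supported by positive evidence, or `NA` when
#' there is none. A preserved ossified process dominates; otherwise a
#' preserved cartilaginous/calcified process, or at least one uncinate
#' scar, implies the mapped state (scars mark the attachment of removable,
#' i.e. cartilaginous-grade, processes).
#'
#' @param n_ribs_examined,n_ribs_with_scar rib counts for the taxon.
#' @param preserved_process process class (see [read_evidence()]).
#' @param process_map named vector from process class to state; see
#'   [default_process_map()].
#' @param scar_state state implied by scar-only evidence (default 1).
#' @return integer state or `NA` (no positive evidence).
#' @export
evidence_state <- function(n_ribs_examined, n_ribs_with_scar,
                           preserved_process,
                           process_map = default_process_map(),
                           scar_state = 1L) {
  preserved_process <- tolower(preserved_process)
  if (!preserved_process %in% PROCESS_CLASSES)
    stop("unknown preserved-process class: ", preserved_process)
  if (!all(names(process_map) == PROCESS_CLASSES))
    stop("process_map must be named over: ",
         paste(PROCESS_CLASSES, collapse = ", "))
  ps <- process_map[[preserved_process]]
  if (!is.na(ps) && ps == 2L) return(2L)
  if (!is.na(ps)) return(as.integer(ps))
  if (n_ribs_with_scar >= 1L) return(as.integer(scar_state))
  NA_integer_
}

.code_table <- function(df, absent_if_min_ribs = Inf,
                        process_map = default_process_map(),
                        scar_state = 1L) {
  agg <- aggregate_evidence(df)
  sets <- vector("list", nrow(agg))
  names(sets) <- agg$taxon
  for (i in seq_len(nrow(agg))) {
    ov <- parse_state_set(agg$override_state[i])
    if (!is.null(ov)) {
      sets[[i]] <- ov
      next
    }
    st <- evidence_state(agg$n_ribs_examined[i], agg$n_ribs_with_scar[i],
                         agg$preserved_process[i], process_map, scar_state)
    if (!is.na(st)) {
      sets[[i]] <- st
    } else if (agg$n_ribs_examined[i] >= absent_if_min_ribs) {
      sets[[i]] <- 0L
    } else {
      sets[[i]] <- STATES
    }
  }
  structure(sets, class = "character_coding")
}

#' Preferred coding: positive evidence or uncertainty
#'
#' A taxon is coded with the single state implied by its evidence if at
#' least one specimen shows an uncinate scar or a preserved process;
#' otherwise its state is uncertain (`{0,1,2}`, written `?`). Expert
#' overrides (e.g. an outgroup with many well-preserved, scar-free ribs)
#' take precedence and are taken from the table's `override_state` column.
#'
#' @param df specimen-evidence data.frame (see [read_evidence()]); rows of
#'   the same taxon are aggregated first.
#' @inheritParams evidence_state
#' @return a `character_coding`: named list of integer state sets.
#' @export
code_preferred <- function(df, process_map = default_process_map(),
                           scar_state = 1L) {
  .code_table(df, absent_if_min_ribs = Inf, process_map = process_map,
              scar_state = scar_state)
}

#' Alternate coding: absence from well-sampled, scar-free taxa
#'
#' Identical to [code_preferred()] except that a taxon with no positive
#' evidence whose examined rib count (regardless of preservation state)
#' reaches `min_ribs` is coded absent (`{0}`) instead of uncertain. This
#' tests the stability of results against treating sustained negative
#' evidence as absence.
#'
#' @inheritParams code_preferred
#' @param min_ribs minimum number of examined ribs required to code
#'   absence (default 5).
#' @return a `character_coding`.
#' @export
code_alternate <- function(df, min_ribs = 5L,
                           process_map = default_process_map(),
                           scar_state = 1L) {
  if (!is.numeric(min_ribs) || length(min_ribs) != 1L || min_ribs < 1)
    stop("'min_ribs' must be a count >= 1")
  .code_table(df, absent_if_min_ribs = min_ribs, process_map = process_map,
              scar_state = scar_state)
}

#' @export
print.character_coding <- function(x, ...) {
  cat("character coding over states {0 absent, 1 cartilaginous, 2 ossified}\n")
  df <- as.data.frame(x)
  print(df, row.names = FALSE)
  invisible(x)
}

#' @export
as.data.frame.character_coding <- function(x, ...) {
  data.frame(taxon = names(x),
             states = vapply(x, format_state_set, character(1L)),
             stringsAsFactors = FALSE)
}

#' Write a character coding as delimited text
#'
#' @param coding a `character_coding`.
#' @param file output path (TSV).
#' @export
write_coding <- function(coding, file) {
  write.table(as.data.frame(coding), file, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(file)
}

#' Read a character coding written by [write_coding()]
#'
#' @param file TSV with columns `taxon`, `states`.
#' @return a `character_coding`.
#' @export
read_coding <- function(file) {
  df <- read.delim(file, stringsAsFactors = FALSE,
                   colClasses = c("character", "character"))
  sets <- lapply(df$states, parse_state_set)
  if (any(vapply(sets, is.null, logical(1L))))
    stop("empty state set in coding file")
  names(sets) <- df$taxon
  structure(sets, class = "character_coding")
}

#' Export a coding as a NEXUS character matrix
#'
#' Single character, symbols `012`, ambiguity in braces, full uncertainty
#' as `?`.
#'
#' @param coding a `character_coding`.
#' @param file output path.
#' @export
write_coding_nexus <- function(coding, file) {
  sym <- vapply(coding, function(v) {
    if (length(v) == length(STATES)) "?"
    else if (length(v) == 1L) as.character(v)
    else paste0("{", paste(v, collapse = ""), "}")
  }, character(1L))
  lab <- gsub("[^A-Za-z0-9_]", "_", names(coding))
  lines <- c(
    "#NEXUS",
    "BEGIN DATA;",
    sprintf("  DIMENSIONS NTAX=%d NCHAR=1;", length(coding)),
    "  FORMAT DATATYPE=STANDARD SYMBOLS=\"012\" MISSING=?;",
    "  MATRIX",
    sprintf("    %s %s", formatC(lab, width = max(nchar(lab)), flag = "-"), sym),
    "  ;",
    "END;")
  writeLines(lines, file)
  invisible(file)
}

# Ntip x 3 indicator matrix in tree tip order; the likelihood-side view of
# a coding (ambiguity = several allowed states)
coding_matrix <- function(coding, tree) {
  if (!inherits(coding, "character_coding"))
    coding <- structure(coding, class = "character_coding")
  miss <- setdiff(tree$tip.label, names(coding))
  if (length(miss))
    stop("tip(s) missing from coding: ", paste(miss, collapse = ", "))
  ntip <- length(tree$tip.label)
  M <- matrix(0, ntip, length(STATES),
              dimnames = list(tree$tip.label, paste0("state", STATES)))
  for (i in seq_len(ntip)) {
    v <- coding[[tree$tip.label[i]]]
    if (length(v) == 0L) stop("empty state set for ", tree$tip.label[i])
    M[i, v + 1L] <- 1
  }
  M
}
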