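#' Parse a newick tree
#'
#' Thin wrapper around [ape::read.tree()] that enforces the invariants the
#' pipeline relies on: a rooted topology, nonnegative branch lengths, unique
#' tip labels. Internal node labels are preserved but unused.
#'
#' @param text a newick string (must end with `;`).
#' @return an [ape::phylo] tree.
#' @export
parse_newick <- function(text) {
  if (!grepl(";", text, fixed = TRUE))
    stop("newick parse error: missing ';' terminator", call. = FALSE)
  n_open <- lengths(regmatches(text, gregexpr("(", text, fixed = TRUE)))
  n_close <- lengths(regmatches(text, gregexpr(")", text, fixed = TRUE)))
  if (n_open != n_close)
    stop(sprintf("newick parse error: %d '(' vs %d ')'", n_open, n_close),
         call. = FALSE)
  tree <- tryCatch(ape::read.tree(text = text),
                   error = function(e) stop("newick parse error: ",
                                            conditionMessage(e), call. = FALSE))
  if (is.null(tree)) stop("newick parse error: unreadable tree", call. = FALSE)
  if (is.null(tree$edge.length))
    stop("newick parse error: tree has no branch lengths", call. = FALSE)
  if (any(tree$edge.length < 0))
    stop("newick parse error: negative branch length", call. = FALSE)
  if (anyDuplicated(tree$tip.label))
    stop("duplicate tip labels in tree", call. = FALSE)
  tree
}

#' Read a newick file
#' @param path path to a newick file.
#' @export
read_newick <- function(path) {
  parse_newick(paste(readLines(path, warn = FALSE), collapse = ""))
}

#' Serialize a tree to newick
#' @param tree an [ape::phylo] object.
#' @param path optional path; when given the string is also written there.
#' @export
write_newick <- function(tree, path = NULL) {
  s <- ape::write.tree(tree)
  if (!is.null(path)) writeLines(s, path)
  invisible(s)
}

#' Metabolic reaction records
#'
#' A reaction record holds a reaction id, its substrate and product compound
#' sets, and a reversibility flag. The on-disk format is tab-separated:
#' `reaction_id <TAB> substrates <TAB> products <TAB> reversible`, compounds
#' joined by `;`, reversible coded 0/1 (or true/false). A leading `otu_id`
#' column turns the file into a combined multi-organism file (see
#' [read_reaction_sets()]).
#'
#' @param reaction_id character scalar.
#' @param substrates,products character vectors of compound ids (non-empty).
#' @param reversible logical scalar.
#' @return a `reaction_record` (a named list).
#' @export
reaction_record <- function(reaction_id, substrates, products,
                            reversible = FALSE) {
  substrates <- unique(as.character(substrates))
  products <- unique(as.character(products))
  if (!length(substrates) || any(!nzchar(substrates)))
    stop("reaction ", reaction_id, ": empty substrate set", call. = FALSE)
  if (!length(products) || any(!nzchar(products)))
    stop("reaction ", reaction_id, ": empty product set", call. = FALSE)
  structure(list(reaction_id = as.character(reaction_id),
                 substrates = substrates, products = products,
                 reversible = isTRUE(as.logical(reversible))),
            class = "reaction_record")
}

parse_reaction_row <- function(fields, line_no) {
  if (length(fields) != 4)
    stop("reaction file line ", line_no, ": expected 4 fields, got ",
         length(fields), call. = FALSE)
  rev <- fields[4]
  rev <- if (rev %in% c("1", "true", "TRUE", "True")) TRUE
         else if (rev %in% c("0", "false", "FALSE", "False")) FALSE
         else stop("reaction file line ", line_no,
                   ": unrecognized reversible flag '", rev, "'", call. = FALSE)
  subs <- strsplit(fields[2], ";", fixed = TRUE)[[1]]
  prods <- strsplit(fields[3], ";", fixed = TRUE)[[1]]
  if (!length(subs) || any(!nzchar(subs)))
    stop("reaction file line ", line_no, ": empty substrate field",
         call. = FALSE)
  if (!length(prods) || any(!nzchar(prods)))
    stop("reaction file line ", line_no, ": empty product field",
         call. = FALSE)
  reaction_record(fields[1], subs, prods, rev)
}

#' Read reaction records
#'
#' @param path tab-separated reaction file (4 columns, see
#'   [reaction_record()]); a header line starting with `reaction_id` is
#'   skipped.
#' @return a list of `reaction_record`s in file order.
#' @export
read_reactions <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) && startsWith(lines[1], "reaction_id"))
    lines <- lines[-1]
  out <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    out[[i]] <- parse_reaction_row(strsplit(lines[i], "\t", fixed = TRUE)[[1]],
                                   i)
  }
  out
}

#' Read a combined per-OTU reaction file
#'
#' Same schema as [read_reactions()] with a leading `otu_id` column; rows are
#' grouped by organism.
#'
#' @param path tab-separated file with columns `otu_id`, `reaction_id`,
#'   `substrates`, `products`, `reversible`.
#' @return a named list: otu id -> list of `reaction_record`s.
#' @export
read_reaction_sets <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) && startsWith(lines[1], "otu_id")) lines <- lines[-1]
  otus <- character(length(lines))
  recs <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(fields) != 5)
      stop("combined reaction file line ", i, ": expected 5 fields",
           call. = FALSE)
    otus[i] <- fields[1]
    recs[[i]] <- parse_reaction_row(fields[-1], i)
  }
  split(recs, factor(otus, levels = unique(otus)))
}

#' Write reaction records
#' @param reactions a list of `reaction_record`s, or a named list of such
#'   lists (combined file with `otu_id` column).
#' @param path output path.
#' @export
write_reactions <- function(reactions, path) {
  fmt <- function(r) paste(r$reaction_id,
                           paste(r$substrates, collapse = ";"),
                           paste(r$products, collapse = ";"),
                           as.integer(r$reversible), sep = "\t")
  if (length(reactions) && is.list(reactions[[1]]) &&
      !inherits(reactions[[1]], "reaction_record")) {
    header <- "otu_id\treaction_id\tsubstrates\tproducts\treversible"
    body <- unlist(lapply(names(reactions), function(o)
      vapply(reactions[[o]], function(r) paste(o, fmt(r), sep = "\t"), "")))
  } else {
    header <- "reaction_id\tsubstrates\tproducts\treversible"
    body <- vapply(reactions, fmt, "")
  }
  writeLines(c(header, body), path)
  invisible(path)
}

#' Write a stage result table or report
#'
#' Data frames are written as tab-separated text with a fixed numeric
#' precision (default 6 significant digits) and deterministic column order;
#' lists are written as JSON. Re-reading reproduces values to that precision.
#'
#' @param results a data.frame (-> tsv) or list (-> JSON).
#' @param path output path.
#' @param digits significant digits for floating-point columns.
#' @export
write_results <- function(results, path, digits = 6) {
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  if (is.data.frame(results)) {
    out <- results
    for (j in seq_along(out)) {
      if (is.double(out[[j]])) out[[j]] <- signif(out[[j]], digits)
    }
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    jsonlite::write_json(results, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  invisible(path)
}
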