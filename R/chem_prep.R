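# Molecule standardisation pipeline:
#   parse -> duplicate check -> (salt strip, neutralise, size/organic
#   filters) -> duplicate check again -> clean records.
# Parsing, SDF handling and InChI generation are delegated to
# ChemmineR/ChemmineOB (OpenBabel); the standardisation rules themselves are
# a deliberately small, documented table (see standardise_molecule), not a
# reimplementation of any full standardiser tool.

# MDL old-style charge codes <-> formal charge
.mdl_code_to_charge <- c(`0` = 0L, `1` = 3L, `2` = 2L, `3` = 1L, `4` = 0L,
                         `5` = -1L, `6` = -2L, `7` = -3L)
.charge_to_mdl_code <- function(q) {
  code <- c(`3` = 1L, `2` = 2L, `1` = 3L, `0` = 0L, `-1` = 5L, `-2` = 6L, `-3` = 7L)
  out <- code[as.character(q)]
  out[is.na(out)] <- 0L
  unname(out)
}

#' Molecular graph of an SDF molecule
#'
#' Heavy-atom graph extracted from a \code{ChemmineR} \code{SDF} object:
#' element symbols, formal charges and a bond table (1-based atom indices,
#' order 1/2/3, 4 = aromatic where the source encodes it).
#'
#' @param sdf A \code{ChemmineR::SDF} object.
#' @return A list with \code{elem} (character), \code{charge} (integer),
#'   \code{bonds} (matrix with columns \code{a1}, \code{a2}, \code{order})
#'   and \code{n} (atom count).
#' @export
molecule_graph <- function(sdf) {
  ab <- ChemmineR::atomblock(sdf)
  bb <- ChemmineR::bondblock(sdf)
  elem <- sub("_.*$", "", rownames(ab))
  charge <- unname(.mdl_code_to_charge[as.character(ab[, "C6"])])
  charge[is.na(charge)] <- 0L
  bb <- as.matrix(bb)
  # bond-less molecules come back as a stub row of zeros without an order column
  bonds <- if (length(bb) > 0 && nrow(bb) > 0 && ncol(bb) >= 3)
    cbind(a1 = as.integer(bb[, 1]), a2 = as.integer(bb[, 2]),
          order = as.integer(bb[, 3]))
  else matrix(integer(0), 0, 3, dimnames = list(NULL, c("a1", "a2", "order")))
  bonds <- bonds[bonds[, 1] >= 1L & bonds[, 2] >= 1L, , drop = FALSE]
  list(elem = elem, charge = charge, bonds = bonds, n = length(elem))
}

# connected components of the heavy-atom graph (label per atom)
.graph_components <- function(g) {
  comp <- seq_len(g$n)
  find <- function(i) { while (comp[i] != i) i <- comp[i]; i }
  if (nrow(g$bonds) > 0)
    for (b in seq_len(nrow(g$bonds))) {
      r1 <- find(g$bonds[b, 1]); r2 <- find(g$bonds[b, 2])
      if (r1 != r2) comp[r2] <- r1
    }
  # path-compress into final labels
  vapply(seq_len(g$n), find, integer(1))
}

# total bond order incident to each atom
.bond_order_sum <- function(g) {
  s <- numeric(g$n)
  if (nrow(g$bonds) > 0)
    for (b in seq_len(nrow(g$bonds))) {
      o <- g$bonds[b, 3]
      if (o == 4L) o <- 1.5
      s[g$bonds[b, 1]] <- s[g$bonds[b, 1]] + o
      s[g$bonds[b, 2]] <- s[g$bonds[b, 2]] + o
    }
  s
}

# Neutralisation rule table, applied atom-wise on the kept fragment:
#   * -1 on O or S with no positively charged neighbour -> 0 (gain H);
#     the neighbour guard preserves charge-separated groups (nitro, N-oxide).
#   * +1 on N or P with total bond order <= 3 (i.e. an implicit H to give)
#     and no negatively charged neighbour -> 0 (lose H).
#   * anything else (quaternary N+, metals, multi-charges) kept as-is.
.neutralise <- function(g) {
  adj <- vector("list", g$n)
  if (nrow(g$bonds) > 0)
    for (b in seq_len(nrow(g$bonds))) {
      adj[[g$bonds[b, 1]]] <- c(adj[[g$bonds[b, 1]]], g$bonds[b, 2])
      adj[[g$bonds[b, 2]]] <- c(adj[[g$bonds[b, 2]]], g$bonds[b, 1])
    }
  bos <- .bond_order_sum(g)
  q <- g$charge
  for (i in seq_len(g$n)) {
    nb_q <- if (length(adj[[i]])) g$charge[adj[[i]]] else integer(0)
    if (q[i] == -1L && g$elem[i] %in% c("O", "S") && !any(nb_q > 0L))
      q[i] <- 0L
    else if (q[i] == 1L && g$elem[i] %in% c("N", "P") && bos[i] <= 3 && !any(nb_q < 0L))
      q[i] <- 0L
  }
  g$charge <- q
  g
}

# rebuild an SDF restricted to `keep` atoms with graph `g`'s charges
.subset_sdf <- function(sdf, g, keep) {
  ab <- ChemmineR::atomblock(sdf)[keep, , drop = FALSE]
  ab[, "C6"] <- .charge_to_mdl_code(g$charge[keep])
  old2new <- match(seq_len(g$n), keep)
  kb <- g$bonds[g$bonds[, 1] %in% keep & g$bonds[, 2] %in% keep, , drop = FALSE]
  bb <- ChemmineR::bondblock(sdf)
  bb <- bb[g$bonds[, 1] %in% keep & g$bonds[, 2] %in% keep, , drop = FALSE]
  if (nrow(bb) > 0) {
    bb[, 1] <- old2new[kb[, 1]]
    bb[, 2] <- old2new[kb[, 2]]
  }
  out <- sdf
  out@atomblock <- ab
  out@bondblock <- bb
  out@datablock <- character(0)
  h <- ChemmineR::header(sdf)
  h["Counts_Line"] <- sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000",
                              nrow(ab), nrow(bb))
  out@header <- h
  out
}

.parse_smiles <- function(smiles) {
  tryCatch({
    sdf <- suppressWarnings(ChemmineR::smiles2sdf(smiles))[[1]]
    if (nrow(ChemmineR::atomblock(sdf)) == 0) NULL else sdf
  }, error = function(e) NULL)
}

.sdf_to_text <- function(sdf) paste0(paste(ChemmineR::sdf2str(sdf), collapse = "\n"), "\n")

# OpenBabel output conversions go through the obabel executable (one
# molecule per call): the in-process string API mangles long outputs such
# as stereo InChIs, while the CLI is reliable.
.obabel_out <- function(sdf, format) {
  tf <- tempfile(fileext = ".sdf")
  on.exit(unlink(tf), add = TRUE)
  writeLines(ChemmineR::sdf2str(sdf), tf)
  out <- tryCatch(
    suppressWarnings(system2("obabel", c("-isdf", tf, paste0("-o", format)),
                             stdout = TRUE, stderr = FALSE)),
    error = function(e) character(0))
  out[nzchar(trimws(out))]
}

.sdf_to_inchi <- function(sdf) {
  out <- .obabel_out(sdf, "inchi")
  hit <- grep("^InChI=", out, value = TRUE)
  if (length(hit) == 0) NA_character_ else hit[[1]]
}

.sdf_to_smiles <- function(sdf) {
  out <- .obabel_out(sdf, "can")
  if (length(out) == 0) return(NA_character_)
  smi <- strsplit(trimws(out[[1]]), "[ \t]")[[1]]
  if (length(smi) == 0 || !nzchar(smi[[1]])) NA_character_ else smi[[1]]
}

#' Standardise one molecule
#'
#' Applies the preprocessing protocol to a single structure: keep the
#' largest covalently connected organic (carbon-containing) fragment,
#' neutralise common charged groups by the documented rule table, and
#' reject structures that are unparseable, contain no organic fragment, or
#' end up with fewer than four heavy atoms.
#'
#' @param smiles A SMILES string, or a \code{ChemmineR::SDF} object.
#' @return A list with \code{status} (\code{"ok"}, \code{"unparseable"},
#'   \code{"non_organic"} or \code{"too_small"}) and, when ok, \code{sdf}
#'   (standardised structure), \code{inchi} and \code{smiles} (canonical,
#'   of the standardised structure).
#' @export
standardise_molecule <- function(smiles) {
  sdf <- if (methods::is(smiles, "SDF")) smiles else .parse_smiles(smiles)
  if (is.null(sdf)) return(list(status = "unparseable"))
  g <- molecule_graph(sdf)
  if (g$n == 0) return(list(status = "unparseable"))
  comp <- .graph_components(g)
  sizes <- table(comp)
  organic <- vapply(names(sizes), function(cc)
    any(g$elem[comp == as.integer(cc)] == "C"), logical(1))
  if (!any(organic)) return(list(status = "non_organic"))
  cand <- names(sizes)[organic]
  keep_comp <- cand[which.max(sizes[cand])]
  keep <- which(comp == as.integer(keep_comp))
  if (length(keep) < 4) return(list(status = "too_small"))
  g <- .neutralise(g)
  std <- .subset_sdf(sdf, g, keep)
  inchi <- .sdf_to_inchi(std)
  if (is.na(inchi)) return(list(status = "unparseable"))
  list(status = "ok", sdf = std, inchi = inchi, smiles = .sdf_to_smiles(std))
}

#' Remove duplicate and label-conflicting records
#'
#' For each InChI carrying both a 0 and a 1 label, all its records are
#' removed; duplicates with agreeing labels are merged to the first-seen
#' record. Output InChIs are unique.
#'
#' @param records A data frame with columns \code{inchi} and \code{label}
#'   (0/1).
#' @return The surviving records, with attribute \code{removed} =
#'   \code{c(conflict = ..., merged = ...)} counting removals.
#' @export
deduplicate <- function(records) {
  stopifnot(all(c("inchi", "label") %in% names(records)))
  n_lab <- tapply(records$label, records$inchi, function(v) length(unique(v)))
  conflicted <- names(n_lab)[n_lab > 1]
  is_conf <- records$inchi %in% conflicted
  kept <- records[!is_conf, , drop = FALSE]
  first <- !duplicated(kept$inchi)
  out <- kept[first, , drop = FALSE]
  attr(out, "removed") <- c(conflict = sum(is_conf), merged = sum(!first))
  out
}

#' Preprocess a raw labelled dataset for one endpoint
#'
#' Full pipeline: records with a missing label for the endpoint are set
#' aside; structures are parsed; the duplicate/conflict rule runs on the raw
#' InChIs; each survivor is standardised
#' (\code{\link{standardise_molecule}}); and the duplicate/conflict rule
#' runs again on the standardised InChIs (salt stripping can merge formerly
#' distinct parents). Every removal is counted in the report, so that
#' \code{nrow(input) == nrow(records) + sum(report)}.
#'
#' @param raw Data frame with columns \code{source_id}, \code{smiles} and a
#'   label column.
#' @param label_col Name of the 0/1/NA label column (default
#'   \code{"label"}).
#' @return A list with \code{records} (data frame: \code{source_id},
#'   \code{smiles}, \code{inchi}, \code{label}) and \code{report} (named
#'   integer vector of removal counts).
#' @export
preprocess_dataset <- function(raw, label_col = "label") {
  report <- c(missing_label = 0L, unparseable = 0L, conflict_pre = 0L,
              duplicate_pre = 0L, non_organic = 0L, too_small = 0L,
              conflict_post = 0L, duplicate_post = 0L)
  empty <- data.frame(source_id = character(0), smiles = character(0),
                      inchi = character(0), label = integer(0))
  if (nrow(raw) == 0) return(list(records = empty, report = report))
  lab <- raw[[label_col]]
  keep <- !is.na(lab) & lab %in% c(0L, 1L)
  report["missing_label"] <- sum(!keep)
  df <- data.frame(source_id = raw$source_id[keep], smiles = raw$smiles[keep],
                   label = as.integer(lab[keep]))
  if (nrow(df) == 0) return(list(records = empty, report = report))

  parsed <- lapply(df$smiles, .parse_smiles)
  ok <- !vapply(parsed, is.null, logical(1))
  raw_inchi <- rep(NA_character_, nrow(df))
  raw_inchi[ok] <- vapply(parsed[ok], .sdf_to_inchi, character(1))
  ok <- ok & !is.na(raw_inchi)
  report["unparseable"] <- sum(!ok)
  df <- df[ok, , drop = FALSE]; parsed <- parsed[ok]
  df$inchi <- raw_inchi[ok]

  dd <- deduplicate(df)
  report["conflict_pre"] <- attr(dd, "removed")[["conflict"]]
  report["duplicate_pre"] <- attr(dd, "removed")[["merged"]]
  parsed <- parsed[match(rownames(dd), rownames(df))]
  df <- dd

  std <- lapply(parsed, standardise_molecule)
  status <- vapply(std, `[[`, character(1), "status")
  report["non_organic"] <- sum(status == "non_organic")
  report["too_small"] <- sum(status == "too_small")
  report["unparseable"] <- report[["unparseable"]] + sum(status == "unparseable")
  ok <- status == "ok"
  df <- df[ok, , drop = FALSE]; std <- std[ok]
  df$inchi <- vapply(std, `[[`, character(1), "inchi")
  df$smiles <- vapply(std, `[[`, character(1), "smiles")

  dd <- deduplicate(df)
  report["conflict_post"] <- attr(dd, "removed")[["conflict"]]
  report["duplicate_post"] <- attr(dd, "removed")[["merged"]]
  df <- dd
  attr(df, "removed") <- NULL
  rownames(df) <- NULL
  list(records = df[, c("source_id", "smiles", "inchi", "label")], report = report)
}

#' Read a SMILES + labels CSV
#'
#' @param path CSV file with a SMILES column, an optional id column and one
#'   0/1 column per endpoint; the string given by \code{missing} (default
#'   \code{"X"}) marks an unavailable label.
#' @param smiles_col,id_col Column names.
#' @param missing Missing-label token.
#' @return Data frame with \code{source_id}, \code{smiles} and one integer
#'   (0/1/NA) column per remaining input column.
#' @export
read_smiles_csv <- function(path, smiles_col = "smiles", id_col = NULL, missing = "X") {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  if (!smiles_col %in% names(df)) stop("no column '", smiles_col, "' in ", path)
  out <- data.frame(
    source_id = if (!is.null(id_col)) df[[id_col]] else sprintf("rec%04d", seq_len(nrow(df))),
    smiles = df[[smiles_col]])
  for (col in setdiff(names(df), c(smiles_col, id_col))) {
    v <- df[[col]]
    v[v == missing] <- NA
    out[[col]] <- as.integer(v)
  }
  out
}

#' Read an SDF file with per-endpoint label data fields
#'
#' @param path SDF file; each molecule's data block holds one field per
#'   endpoint with value 0, 1 or the \code{missing} token.
#' @param endpoints Character vector of data-field names to extract; default
#'   all fields.
#' @param missing Missing-label token (default \code{"X"}).
#' @return Data frame as \code{\link{read_smiles_csv}}, with SMILES
#'   regenerated from the structures.
#' @export
read_sdf_dataset <- function(path, endpoints = NULL, missing = "X") {
  sdfs <- ChemmineR::read.SDFset(path)
  ids <- ChemmineR::sdfid(sdfs)
  smiles <- vapply(seq_along(sdfs), function(i) .sdf_to_smiles(sdfs[[i]]), character(1))
  out <- data.frame(source_id = ids, smiles = smiles)
  dbs <- lapply(seq_along(sdfs), function(i) ChemmineR::datablock(sdfs[[i]]))
  if (is.null(endpoints))
    endpoints <- unique(unlist(lapply(dbs, names)))
  for (ep in endpoints) {
    v <- vapply(dbs, function(db) if (ep %in% names(db)) db[[ep]] else missing, character(1))
    v[v == missing] <- NA
    out[[ep]] <- as.integer(v)
  }
  out
}

#' Write a cleaned dataset and its removal report
#'
#' @param prep Result of \code{\link{preprocess_dataset}}.
#' @param records_path,report_path Output CSV paths (either may be
#'   \code{NULL} to skip).
#' @param batch Batch tag written with the records (train/test/score).
#' @export
write_clean_dataset <- function(prep, records_path = NULL, report_path = NULL,
                                batch = "train") {
  if (!is.null(records_path)) {
    rec <- prep$records
    rec$batch <- batch
    utils::write.csv(rec, records_path, row.names = FALSE)
  }
  if (!is.null(report_path)) {
    utils::write.csv(data.frame(reason = names(prep$report),
                                removed = as.integer(prep$report)),
                     report_path, row.names = FALSE)
  }
  invisible(prep)
}
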