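#' Read molecular poses from SDF, MOL or PDB
#'
#' SDF/MOL (V2000) records are parsed with ChemmineR; each record becomes
#' one [conformer] in file order, hydrogens retained. `pdb-ligand` extracts
#' the HETATM records of one residue from a PDB file (see
#' [read_pdb_ligand]).
#'
#' @param path path to the file.
#' @param format one of "sdf", "mol", "pdb-ligand".
#' @param resid residue name of the ligand, required for "pdb-ligand".
#' @return A single `conformer` for one-record files, otherwise a list of
#'   `conformer`s in record order.
#' @export
read_pose_file <- function(path, format = c("sdf", "mol", "pdb-ligand"),
                           resid = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "pdb-ligand") {
    if (is.null(resid)) stop("'resid' is required for pdb-ligand format")
    return(read_pdb_ligand(path, resid))
  }
  sdfset <- tryCatch(ChemmineR::read.SDFset(path),
                     error = function(e)
                       stop("failed to parse ", path, ": ", conditionMessage(e)))
  confs <- lapply(seq_along(ChemmineR::sdfid(sdfset)), function(i)
    sdf_to_conformer(sdfset[[i]]))
  if (format == "mol" && length(confs) != 1L)
    stop("MOL file must contain exactly one record, found ", length(confs))
  if (length(confs) == 1L) confs[[1L]] else confs
}

sdf_to_conformer <- function(sdf) {
  ab <- ChemmineR::atomblock(sdf)
  bb <- ChemmineR::bondblock(sdf)
  elements <- sub("_.*$", "", rownames(ab))
  bonds <- if (is.matrix(bb) && nrow(bb)) {
    data.frame(from = as.integer(bb[, 1]), to = as.integer(bb[, 2]),
               order = as.integer(bb[, 3]))
  } else NULL
  name <- ChemmineR::header(sdf)[["Molecule_Name"]]
  conformer(elements, ab[, 1:3, drop = FALSE], bonds,
            if (is.null(name) || is.na(name)) "" else name)
}

#' Extract a ligand conformer from a PDB file
#'
#' Selects the HETATM records whose residue name matches `resid`. When
#' alternate locations are present, the highest-occupancy altloc is kept
#' (ties resolved to the first in file order). No bonds are inferred.
#'
#' @param path PDB file path.
#' @param resid three-letter residue name of the ligand (e.g. "9JU").
#' @return A `conformer` (bond-less) in the receptor coordinate frame.
#' @export
read_pdb_ligand <- function(path, resid) {
  pdb <- bio3d::read.pdb(path)
  at <- pdb$atom
  at <- at[at$type == "HETATM" & at$resid == resid, , drop = FALSE]
  if (!nrow(at)) stop("no HETATM records with residue name ", resid)
  alt <- at$alt
  alt[is.na(alt)] <- ""
  if (any(nzchar(alt))) {
    keep <- unlist(lapply(split(seq_len(nrow(at)), at$elety), function(i) {
      occ <- at$o[i]
      occ[is.na(occ)] <- 1
      i[which.max(occ)]  # which.max keeps the first on ties
    }))
    at <- at[sort(keep), , drop = FALSE]
  }
  elem <- at$elesy
  if (is.null(elem) || all(is.na(elem)) || !any(nzchar(elem[!is.na(elem)])))
    elem <- sub("[0-9'\"]*$", "", at$elety)
  conformer(elem, cbind(at$x, at$y, at$z), NULL, resid)
}

#' Write conformers to an SDF file
#'
#' Emits one V2000 record per conformer (via ChemmineR), optionally with a
#' data field per record. Coordinates are written at 1e-5 Angstrom
#' precision, so a write/read round trip preserves them to better than
#' 1e-4 Angstrom.
#'
#' @param confs a `conformer` or list of conformers.
#' @param path output file path.
#' @param data optional named list (one element per conformer) of named
#'   character vectors written as SDF data fields.
#' @return `path`, invisibly.
#' @export
write_pose_file <- function(confs, path, data = NULL) {
  if (inherits(confs, "conformer")) confs <- list(confs)
  sdfs <- lapply(seq_along(confs), function(i) {
    conformer_to_sdf(confs[[i]],
                     if (is.null(data)) character() else data[[i]])
  })
  ids <- paste0("CMP", seq_along(sdfs))
  names(sdfs) <- ids
  sdfset <- methods::new(methods::getClass("SDFset", where = asNamespace("ChemmineR")),
                         SDF = sdfs, ID = ids)
  ChemmineR::write.SDF(sdfset, file = path)
  invisible(path)
}

conformer_to_sdf <- function(conf, datablock = character()) {
  n <- n_atoms(conf)
  nb <- nrow(conf$bonds)
  ab <- cbind(conf$coords, matrix(0, n, 13))
  rownames(ab) <- paste(conf$elements, seq_len(n), sep = "_")
  colnames(ab) <- paste0("C", 1:16)
  bb <- if (nb) {
    m <- cbind(conf$bonds$from, conf$bonds$to, conf$bonds$order,
               matrix(0, nb, 4))
    rownames(m) <- as.character(seq_len(nb))
    colnames(m) <- paste0("C", 1:7)
    m
  } else {
    matrix(numeric(), 0, 7, dimnames = list(NULL, paste0("C", 1:7)))
  }
  hdr <- c(Molecule_Name = conf$name, Source = "  screenperm", Comment = "",
           Counts_Line = sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000",
                                 n, nb))
  if (!length(datablock)) datablock <- character()
  methods::new(methods::getClass("SDF", where = asNamespace("ChemmineR")),
               header = hdr, atomblock = ab, bondblock = bb,
               datablock = datablock)
}

#' Read a labelled score table
#'
#' Reads a delimited text file (comma or tab, header row) holding one row
#' per compound: an id column, an active/decoy label column, and one
#' numeric column per docking/scoring combination. Missing scores (empty
#' fields or NA) are preserved as `NA`, so a compound a docking run failed
#' to score stays distinguishable from a score of 0 and is excluded only
#' from that combination's rankings.
#'
#' @param path delimited text file.
#' @param id_col,label_col column names for compound id and label.
#' @param score_cols character vector of score column names; default all
#'   remaining columns.
#' @param sep field separator; inferred from the extension by default
#'   ("," for .csv, tab otherwise).
#' @return A `score_table`: a data frame with columns `compound_id`,
#'   `label`, then one numeric column per combination.
#' @export
read_score_table <- function(path, id_col = "compound_id",
                             label_col = "label", score_cols = NULL,
                             sep = NULL) {
  if (is.null(sep)) sep <- if (grepl("\\.csv$", path, TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (!nrow(df)) stop("score table is empty: ", path)
  stopifnot(id_col %in% names(df), label_col %in% names(df))
  if (is.null(score_cols))
    score_cols <- setdiff(names(df), c(id_col, label_col))
  score_table(df[[id_col]], df[[label_col]],
              lapply(stats::setNames(score_cols, score_cols),
                     function(cn) as.numeric(df[[cn]])))
}

#' Construct a labelled score table
#'
#' @param compound_id character vector of unique compound ids.
#' @param label "active" or "decoy" per compound.
#' @param scores named list of numeric vectors (NA = unscored), one per
#'   docking/scoring combination.
#' @return A `score_table` data frame.
#' @export
score_table <- function(compound_id, label, scores) {
  compound_id <- as.character(compound_id)
  if (anyDuplicated(compound_id))
    stop("duplicate compound ids: ",
         paste(unique(compound_id[duplicated(compound_id)]), collapse = ", "))
  if (!all(label %in% c("active", "decoy")))
    stop("labels must be 'active' or 'decoy'; found: ",
         paste(setdiff(unique(label), c("active", "decoy")), collapse = ", "))
  df <- data.frame(compound_id = compound_id, label = label,
                   stringsAsFactors = FALSE, check.names = FALSE)
  for (cn in names(scores)) {
    v <- scores[[cn]]
    stopifnot(length(v) == nrow(df))
    df[[cn]] <- as.numeric(v)
  }
  class(df) <- c("score_table", "data.frame")
  df
}

#' Write a score table to delimited text
#'
#' @param table a `score_table`.
#' @param path output path (.csv writes comma-separated, else tab).
#' @return `path`, invisibly.
#' @export
write_score_table <- function(table, path) {
  sep <- if (grepl("\\.csv$", path, TRUE)) "," else "\t"
  utils::write.table(table, path, sep = sep, row.names = FALSE,
                     quote = FALSE, na = "")
  invisible(path)
}

#' Names of the score columns of a score table
#' @param table a `score_table`.
#' @return character vector of combination names.
#' @export
score_columns <- function(table)
  setdiff(names(table), c("compound_id", "label"))
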