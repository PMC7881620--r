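#' Read one representative atom per residue from a structure file
#'
#' Parses a PDB or mmCIF file and extracts the coordinate of a single
#' representative atom (by default the C-alpha) for every polymer residue of
#' one chain. Alternate locations are resolved to the highest-occupancy
#' record, ties going to the first alternate-location identifier. Residues
#' that lack the representative atom are omitted with a warning.
#'
#' @param path Path to a PDB (\code{.pdb}, \code{.ent}) or mmCIF
#'   (\code{.cif}, \code{.mmcif}) file.
#' @param chain Chain identifier to extract.
#' @param atom_name Name of the representative atom (default \code{"CA"};
#'   use e.g. \code{"C1'"} for nucleic acids).
#' @return A data frame with columns \code{chain}, \code{resno},
#'   \code{insert}, \code{x}, \code{y}, \code{z}, one row per residue in
#'   file order.
#' @export
load_conformation <- function(path, chain, atom_name = "CA") {
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  pdb <- tryCatch(
    if (ext %in% c("cif", "mmcif")) {
      bio3d::read.cif(path, verbose = FALSE)
    } else {
      bio3d::read.pdb(path, rm.alt = FALSE, verbose = FALSE)
    },
    error = function(e) stop("cannot parse structure file '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  atoms <- pdb$atom
  atoms <- atoms[atoms$type == "ATOM", , drop = FALSE]  # polymer only
  chains <- unique(atoms$chain)
  if (!chain %in% chains) {
    stop("chain '", chain, "' not found in ", path,
         "; available chains: ", paste(chains, collapse = ", "))
  }
  atoms <- atoms[atoms$chain == chain, , drop = FALSE]
  ins <- ifelse(is.na(atoms$insert), "", atoms$insert)
  res_key <- paste(atoms$resno, ins, sep = "|")
  all_res <- unique(res_key)

  ca <- atoms[atoms$elety == atom_name, , drop = FALSE]
  ca_ins <- ifelse(is.na(ca$insert), "", ca$insert)
  ca_key <- paste(ca$resno, ca_ins, sep = "|")
  # resolve altlocs: highest occupancy, ties -> first altloc identifier
  keep <- vapply(split(seq_len(nrow(ca)), factor(ca_key, levels = unique(ca_key))),
                 function(idx) {
                   if (length(idx) == 1L) return(idx)
                   occ <- ca$o[idx]
                   occ[is.na(occ)] <- 1
                   idx <- idx[occ == max(occ)]
                   alt <- ca$alt[idx]
                   alt[is.na(alt)] <- ""
                   idx[order(alt)][1L]
                 }, integer(1))
  ca <- ca[sort(unname(keep)), , drop = FALSE]

  n_missing <- length(all_res) - nrow(ca)
  if (n_missing > 0) {
    warning(n_missing, " residue(s) in chain ", chain,
            " lack atom '", atom_name, "' and were omitted")
  }
  data.frame(chain  = ca$chain,
             resno  = ca$resno,
             insert = ifelse(is.na(ca$insert), "", ca$insert),
             x = ca$x, y = ca$y, z = ca$z,
             stringsAsFactors = FALSE)
}

residue_key <- function(df) paste(df$chain, df$resno, df$insert, sep = "|")

#' Assemble a multi-conformation ensemble on a common residue set
#'
#' Combines two or more per-residue coordinate tables (as returned by
#' \code{\link{load_conformation}}) into a conformational ensemble. Residue
#' correspondence defaults to identity on (chain, author residue number,
#' insertion code): only residues present in every conformation are kept,
#' ordered as in the first conformation. Alternatively an explicit mapping
#' table aligns residues positionally, one column per conformation holding
#' the author residue identifier (\code{"-"} marks a gap; gapped rows are
#' dropped).
#'
#' @param conformations List (length >= 2) of residue-coordinate data frames.
#' @param mapping Optional data frame with one column per conformation; row i
#'   gives the residue identifier (\code{"chain|resno|insert"} or plain
#'   \code{resno}) of position i in each conformation, \code{"-"} for a gap.
#' @param source_labels Optional character vector of provenance labels.
#' @return An object of class \code{conformation_ensemble}: a list with
#'   \code{coords} (array M x N x 3, Angstrom), \code{residue_ids} (data
#'   frame chain/resno/insert), \code{source_labels}.
#' @export
build_ensemble <- function(conformations, mapping = NULL, source_labels = NULL) {
  M <- length(conformations)
  if (M < 2) stop("need at least 2 conformations")
  if (is.null(source_labels)) source_labels <- paste0("conformation_", seq_len(M))

  keys <- lapply(conformations, residue_key)
  if (is.null(mapping)) {
    common <- Reduce(intersect, keys)
    if (length(common) < 3) stop("insufficient shared residues (need >= 3, got ",
                                 length(common), ")")
    order1 <- keys[[1]][keys[[1]] %in% common]
    idx <- lapply(keys, function(k) match(order1, k))
    n_dropped <- sum(vapply(keys, length, 1L)) - M * length(order1)
    if (n_dropped > 0) {
      message("build_ensemble: dropped ", n_dropped,
              " residue row(s) outside the common residue set")
    }
  } else {
    if (ncol(mapping) != M) stop("mapping must have one column per conformation")
    map <- as.data.frame(lapply(mapping, as.character), stringsAsFactors = FALSE)
    ok <- rowSums(map == "-") == 0
    map <- map[ok, , drop = FALSE]
    if (nrow(map) < 3) stop("insufficient shared residues (need >= 3, got ",
                            nrow(map), ")")
    idx <- lapply(seq_len(M), function(m) {
      k <- keys[[m]]
      hit <- match(map[[m]], k)
      if (anyNA(hit)) {
        # allow bare residue numbers in the mapping table
        hit <- match(map[[m]], as.character(conformations[[m]]$resno))
      }
      if (anyNA(hit)) stop("mapping column ", m, " names residues absent from ",
                           "conformation ", m)
      hit
    })
    order1 <- keys[[1]][idx[[1]]]
  }

  N <- length(idx[[1]])
  coords <- array(NA_real_, dim = c(M, N, 3))
  for (m in seq_len(M)) {
    df <- conformations[[m]][idx[[m]], , drop = FALSE]
    coords[m, , ] <- as.matrix(df[, c("x", "y", "z")])
  }
  if (any(!is.finite(coords))) stop("non-finite coordinates in ensemble")
  ids <- conformations[[1]][match(order1, keys[[1]]), c("chain", "resno", "insert")]
  rownames(ids) <- NULL
  structure(list(coords = coords, residue_ids = ids,
                 source_labels = source_labels),
            class = "conformation_ensemble")
}

#' @export
print.conformation_ensemble <- function(x, ...) {
  cat("Conformational ensemble: ", dim(x$coords)[2], " residues x ",
      dim(x$coords)[1], " conformations\n", sep = "")
  invisible(x)
}

n_residues <- function(ensemble) dim(ensemble$coords)[2]
n_conformations <- function(ensemble) dim(ensemble$coords)[1]

validate_ensemble <- function(ensemble) {
  if (!inherits(ensemble, "conformation_ensemble"))
    stop("not a conformation_ensemble")
  d <- dim(ensemble$coords)
  if (length(d) != 3 || d[3] != 3) stop("coords must be an M x N x 3 array")
  if (d[1] < 2) stop("need at least 2 conformations")
  if (d[2] < 3) stop("need at least 3 residues")
  if (any(!is.finite(ensemble$coords))) stop("non-finite coordinates")
  key <- residue_key(ensemble$residue_ids)
  if (anyDuplicated(key)) stop("duplicate residue identifiers")
  invisible(ensemble)
}

#' Write an ensemble to a multi-model PDB file
#'
#' Each conformation becomes one MODEL with a single representative atom
#' (CA) per residue, carrying the ensemble's author residue numbering.
#'
#' @param ensemble A \code{conformation_ensemble}.
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
write_ensemble_pdb <- function(ensemble, path) {
  validate_ensemble(ensemble)
  M <- n_conformations(ensemble)
  ids <- ensemble$residue_ids
  lines <- character(0)
  for (m in seq_len(M)) {
    tmp <- tempfile(fileext = ".pdb")
    N <- nrow(ids)
    bio3d::write.pdb(file = tmp,
                     xyz = as.vector(t(ensemble$coords[m, , ])),
                     resno = ids$resno,
                     chain = ids$chain,
                     insert = ifelse(ids$insert == "", NA, ids$insert),
                     resid = rep("ALA", N), elety = rep("CA", N), end = FALSE)
    body <- readLines(tmp)
    unlink(tmp)
    body <- body[grepl("^ATOM", body)]
    lines <- c(lines, sprintf("MODEL     %4d", m), body, "ENDMDL")
  }
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Read a multi-model PDB file as an ensemble
#'
#' @param path Multi-model PDB path.
#' @param chain Chain to extract (default first chain found).
#' @param atom_name Representative atom name.
#' @return A \code{conformation_ensemble}.
#' @export
read_ensemble_pdb <- function(path, chain = NULL, atom_name = "CA") {
  pdb <- bio3d::read.pdb(path, multi = TRUE, rm.alt = FALSE, verbose = FALSE)
  atoms <- pdb$atom[pdb$atom$type == "ATOM", , drop = FALSE]
  if (is.null(chain)) chain <- atoms$chain[1]
  sel <- atoms$chain == chain & atoms$elety == atom_name
  if (!any(sel)) stop("no '", atom_name, "' atoms for chain ", chain)
  xyz <- pdb$xyz            # matrix: models x (3 * natoms)
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  M <- nrow(xyz)
  if (M < 2) stop("need a multi-model PDB with >= 2 MODEL records")
  at_idx <- which(pdb$atom$type == "ATOM" & pdb$atom$chain == chain &
                  pdb$atom$elety == atom_name)
  N <- length(at_idx)
  coords <- array(NA_real_, dim = c(M, N, 3))
  for (m in seq_len(M)) {
    mat <- matrix(xyz[m, ], ncol = 3, byrow = TRUE)
    coords[m, , ] <- mat[at_idx, , drop = FALSE]
  }
  sub <- pdb$atom[at_idx, ]
  ids <- data.frame(chain = sub$chain, resno = sub$resno,
                    insert = ifelse(is.na(sub$insert), "", sub$insert),
                    stringsAsFactors = FALSE)
  structure(list(coords = coords, residue_ids = ids,
                 source_labels = paste0(basename(path), ":model", seq_len(M))),
            class = "conformation_ensemble")
}

#' Read a residue-correspondence mapping table
#'
#' Tab-separated file with one column per conformation; each row holds the
#' author residue identifiers that correspond across conformations, with
#' \code{"-"} marking a gap.
#'
#' @param path TSV path.
#' @return A data frame suitable for \code{\link{build_ensemble}}'s
#'   \code{mapping} argument.
#' @export
read_mapping_tsv <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    colClasses = "character", check.names = FALSE)
}
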