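#' Read a pocket bundle from its on-disk parts
#'
#' Assembles a [new_pocket_bundle()] from a PDB structure, a pocket
#' definition table, a sequence profile, a secondary-structure track, and
#' template ligands placed in the protein frame. All per-residue tracks are
#' aligned by residue id (chain + author numbering), so row order in the
#' input files is irrelevant.
#'
#' @section Pocket file dialect:
#' Tab-separated with comment headers:
#' \preformatted{
#' # center <tab> x <tab> y <tab> z
#' # props <tab> MW <tab> logP <tab> PSA <tab> HBD <tab> HBA
#' chain <tab> resseq <tab> icode <tab> aa <tab> binding_prob}
#'
#' @section Profile dialect:
#' ASCII table, one row per residue: `pos aa` followed by 20 values in the
#' order `A R N D C Q E G H I L K M F P S T W Y V`. Values may be
#' frequencies or log-odds; which was read is auto-detected (any negative
#' value, or rows not summing to ~1, means log-odds) and recorded.
#'
#' @section Secondary-structure dialect:
#' ss2-style whitespace table: `pos aa state p_coil p_helix p_extended`.
#'
#' @param structure_path PDB file of the target protein (first model only).
#' @param pocket_path Pocket definition TSV (see dialect above).
#' @param profile_path Per-residue sequence profile.
#' @param ss_path Per-residue secondary-structure probabilities.
#' @param ligand_paths Character vector of SDF files with template ligands.
#' @param bound_ligand_path Optional SDF with the bound ligand (evaluation).
#' @return A `pocket_bundle`.
#' @export
read_pocket_bundle <- function(structure_path, pocket_path, profile_path,
                               ss_path, ligand_paths,
                               bound_ligand_path = NULL) {
  for (f in c(structure_path, pocket_path, profile_path, ss_path,
              ligand_paths, bound_ligand_path)) {
    if (!file.exists(f)) abort(paste("file not found:", f))
  }
  pk <- .read_pocket_file(pocket_path)
  res <- .structure_residues(structure_path)
  key <- paste0(pk$table$chain, ":", pk$table$resseq, pk$table$icode)
  hit <- match(key, res$resid)
  if (anyNA(hit)) {
    abort(paste("residue(s) not found in structure:",
                paste(key[is.na(hit)], collapse = ", ")))
  }
  r <- res[hit, ]
  r$aa <- pk$table$aa
  r$binding_prob <- pk$table$binding_prob

  prof <- .read_profile(profile_path)
  ss <- .read_ss2(ss_path)
  pidx <- .match_track(key, pk$table$resseq, prof$pos)
  if (anyNA(pidx)) abort(paste("profile missing residue(s):",
                               paste(key[is.na(pidx)], collapse = ", ")))
  sidx <- .match_track(key, pk$table$resseq, ss$pos)
  if (anyNA(sidx)) abort(paste("secondary structure missing residue(s):",
                               paste(key[is.na(sidx)], collapse = ", ")))
  r$profile <- lapply(pidx, function(k) setNames(prof$values[k, ], AA20))
  r$ss_h <- ss$h[sidx]; r$ss_e <- ss$e[sidx]; r$ss_c <- ss$c[sidx]

  pocket <- new_pocket(r, center = pk$center, props = pk$props,
                       profile_kind = prof$kind)
  templates <- unlist(lapply(ligand_paths, read_ligand_sdf), recursive = FALSE)
  bound <- if (!is.null(bound_ligand_path))
    read_ligand_sdf(bound_ligand_path)[[1]] else NULL
  new_pocket_bundle(pocket, templates, bound)
}

# tracks may be keyed "chain:resseq" or bare resseq
.match_track <- function(key, resseq, pos) {
  hit <- match(key, pos)
  miss <- is.na(hit)
  hit[miss] <- match(as.character(resseq[miss]), pos)
  hit
}

.read_pocket_file <- function(path) {
  lines <- readLines(path)
  center <- props <- NULL
  for (ln in grep("^#", lines, value = TRUE)) {
    f <- strsplit(sub("^#\\s*", "", ln), "\t")[[1]]
    if (f[1] == "center") center <- as.numeric(f[2:4])
    if (f[1] == "props") props <- as.numeric(f[2:6])
  }
  body <- lines[!grepl("^#", lines) & nzchar(lines)]
  con <- textConnection(body)
  on.exit(close(con))
  tab <- utils::read.delim(con, colClasses = c(icode = "character"))
  need <- c("chain", "resseq", "icode", "aa", "binding_prob")
  if (!all(need %in% names(tab)))
    abort(paste("pocket file must have columns:", paste(need, collapse = ", ")))
  tab$icode[is.na(tab$icode)] <- ""
  list(table = as_tibble(tab), center = center, props = props)
}

.read_profile <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^#", lines) & nzchar(trimws(lines))
  rows <- which(keep)
  first <- strsplit(trimws(lines[rows[1]]), "\\s+")[[1]]
  if (identical(first[1], "pos")) rows <- rows[-1]  # optional header line
  pos <- character(length(rows))
  vals <- matrix(NA_real_, length(rows), 20)
  for (k in seq_along(rows)) {
    f <- strsplit(trimws(lines[rows[k]]), "\\s+")[[1]]
    v <- suppressWarnings(as.numeric(f[3:22]))
    if (length(f) < 22 || anyNA(v))
      abort(sprintf("unparseable profile row at line %d of %s",
                    rows[k], path))
    pos[k] <- f[1]
    vals[k, ] <- v
  }
  kind <- if (any(vals < 0) || any(abs(rowSums(vals) - 1) > 0.1))
    "logodds" else "frequency"
  list(pos = pos, values = vals, kind = kind)
}

.read_ss2 <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^#", lines) & nzchar(trimws(lines))
  rows <- which(keep)
  first <- strsplit(trimws(lines[rows[1]]), "\\s+")[[1]]
  if (identical(first[1], "pos")) rows <- rows[-1]
  pos <- character(length(rows))
  p <- matrix(NA_real_, length(rows), 3)
  for (k in seq_along(rows)) {
    f <- strsplit(trimws(lines[rows[k]]), "\\s+")[[1]]
    v <- suppressWarnings(as.numeric(f[4:6]))
    if (length(f) < 6 || anyNA(v))
      abort(sprintf("unparseable ss2 row at line %d of %s", rows[k], path))
    pos[k] <- f[1]
    p[k, ] <- v
  }
  list(pos = pos, c = p[, 1], h = p[, 2], e = p[, 3])
}

# per-residue geometry from a PDB file: Calpha, Cbeta and the side-chain
# heavy-atom centroid (glycine falls back to Calpha, alanine to Cbeta)
.structure_residues <- function(path) {
  pdb <- bio3d::read.pdb(path, multi = FALSE, verbose = FALSE)
  at <- pdb$atom
  at <- at[at$type == "ATOM" & !at$elesy %in% "H", ]
  grp <- paste0(at$chain, ":", at$resno,
                ifelse(is.na(at$insert) | at$insert == "", "", at$insert))
  out <- lapply(split(seq_len(nrow(at)), factor(grp, levels = unique(grp))),
                function(idx) {
    a <- at[idx, ]
    ca <- a[a$elety == "CA", c("x", "y", "z")]
    if (nrow(ca) == 0) return(NULL)
    cb <- a[a$elety == "CB", c("x", "y", "z")]
    scl <- a[!a$elety %in% c("N", "CA", "C", "O", "CB", "OXT"),
             c("x", "y", "z")]
    sc <- if (nrow(scl)) colMeans(scl)
          else if (nrow(cb)) unlist(cb[1, ])
          else unlist(ca[1, ])
    cbv <- if (nrow(cb)) unlist(cb[1, ]) else unlist(ca[1, ])
    tibble(chain = a$chain[1], resseq = a$resno[1],
           icode = ifelse(is.na(a$insert[1]) | a$insert[1] == "",
                          "", a$insert[1]),
           ca_x = ca$x[1], ca_y = ca$y[1], ca_z = ca$z[1],
           cb_x = cbv[1], cb_y = cbv[2], cb_z = cbv[3],
           sc_x = sc[1], sc_y = sc[2], sc_z = sc[3])
  })
  res <- bind_rows(out[!vapply(out, is.null, logical(1))])
  res$resid <- paste0(res$chain, ":", res$resseq, res$icode)
  res
}

#' Read ligands from an SDF file
#'
#' Parses every molecule in a V2000 SDF file (via ChemmineR), dropping
#' hydrogens.
#'
#' @param path SDF file.
#' @return List of `ligand` objects.
#' @export
read_ligand_sdf <- function(path) {
  set <- ChemmineR::read.SDFset(path)
  lapply(seq_along(ChemmineR::cid(set)), function(k) {
    sdf <- set[[k]]
    ab <- ChemmineR::atomblock(sdf)
    elem <- sub("_.*$", "", rownames(ab))
    heavy <- elem != "H"
    if (sum(heavy) < 3)
      abort(paste("ligand with fewer than 3 heavy atoms in", path))
    idx_map <- cumsum(heavy)
    bb <- ChemmineR::bondblock(sdf)
    bonds <- tibble(from = integer(), to = integer(), order = integer())
    if (!is.null(bb) && nrow(bb)) {
      f <- as.integer(bb[, 1]); g <- as.integer(bb[, 2])
      keep <- heavy[f] & heavy[g]
      bonds <- tibble(from = idx_map[f[keep]], to = idx_map[g[keep]],
                      order = as.integer(bb[keep, 3]))
    }
    new_ligand(tibble(elem = elem[heavy],
                      x = ab[heavy, 1], y = ab[heavy, 2], z = ab[heavy, 3]),
               bonds, name = ChemmineR::sdfid(sdf))
  })
}

#' Write ligands to an SDF file
#'
#' @param ligands A `ligand` or list of ligands.
#' @param path Output SDF file.
#' @return `path`, invisibly.
#' @export
write_ligand_sdf <- function(ligands, path) {
  if (inherits(ligands, "ligand")) ligands <- list(ligands)
  sdfs <- lapply(ligands, function(l) {
    n <- nrow(l$atoms); nb <- nrow(l$bonds)
    ab <- cbind(as.matrix(l$atoms[, c("x", "y", "z")]), matrix(0, n, 12))
    rownames(ab) <- paste0(l$atoms$elem, "_", seq_len(n))
    colnames(ab) <- paste0("C", 1:15)
    bb <- cbind(matrix(c(l$bonds$from, l$bonds$to, l$bonds$order),
                       ncol = 3), matrix(0, nb, 4))
    rownames(bb) <- as.character(seq_len(nb))
    colnames(bb) <- paste0("C", 1:7)
    h <- c(Molecule_Name = l$name, Source = "  pocketalign", Comment = "",
           Counts_Line = sprintf("%3d%3d  0     0  0  0  0  0  0999 V2000",
                                 n, nb))
    new("SDF", header = h, atomblock = ab, bondblock = bb,
        datablock = character(0))
  })
  set <- new("SDFset", SDF = sdfs,
             ID = vapply(ligands, function(l) l$name, character(1)))
  ChemmineR::write.SDF(set, file = path)
  invisible(path)
}

#' Write an alignment report
#'
#' Emits a self-describing TSV (residue-pair section, rotation, translation,
#' the six pocket-level features and similarity probability) plus a JSON
#' summary next to it. Round-trips through [read_alignment_report()].
#'
#' @param alignment A `pocket_alignment`.
#' @param record A one-row similarity record tibble (see
#'   [similarity_features()]); may be `NULL` for alignment-only reports.
#' @param out Output TSV path; the JSON summary is written to
#'   `paste0(out, ".json")`.
#' @return `out`, invisibly.
#' @export
write_alignment_report <- function(alignment, record, out) {
  pairs <- tidy(alignment)
  if (nrow(pairs) == 0) abort("cannot write an empty alignment")
  ok <- tryCatch({ con <- file(out, "w"); TRUE },
                 error = function(e) FALSE)
  if (!ok) abort(paste("cannot write to", out))
  on.exit(close(con))
  tr <- attr(alignment, "transform")
  writeLines(c(
    "# pocketalign alignment report v1",
    sprintf("# n\t%d\tm\t%d", attr(alignment, "n"), attr(alignment, "m")),
    sprintf("# total_cost\t%.10g", attr(alignment, "total_cost")),
    sprintf("# pocket_rmsd\t%.10g", attr(alignment, "pocket_rmsd")),
    paste0("# rotation\t",
           paste(sprintf("%.10g", t(tr$rotation)), collapse = "\t")),
    paste0("# translation\t",
           paste(sprintf("%.10g", tr$translation), collapse = "\t"))
  ), con)
  if (!is.null(record)) {
    for (f in intersect(c("f_rms", "f_svr", "f_svc", "f_tau", "f_pcf",
                          "f_pms", "probability"), names(record))) {
      writeLines(sprintf("# %s\t%.10g", f, record[[f]][1]), con)
    }
  }
  writeLines("i\tj\tdist", con)
  writeLines(sprintf("%d\t%d\t%.10g", pairs$i, pairs$j, pairs$dist), con)
  close(con); on.exit()
  json <- list(n = attr(alignment, "n"), m = attr(alignment, "m"),
               total_cost = attr(alignment, "total_cost"),
               pocket_rmsd = attr(alignment, "pocket_rmsd"),
               pairs = as.data.frame(pairs))
  if (!is.null(record)) json$features <- as.list(record[1, ])
  jsonlite::write_json(json, paste0(out, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(out)
}

#' Read an alignment report written by [write_alignment_report()]
#'
#' @param path Report TSV path.
#' @return List with `alignment` (a `pocket_alignment`) and `record`
#'   (one-row tibble of features, or `NULL`).
#' @export
read_alignment_report <- function(path) {
  lines <- readLines(path)
  meta <- list()
  for (ln in grep("^#", lines, value = TRUE)) {
    f <- strsplit(sub("^#\\s*", "", ln), "\t")[[1]]
    if (f[1] == "n") meta$n <- as.integer(f[2])
    if (f[1] == "n") meta$m <- as.integer(f[4])
    if (f[1] %in% c("total_cost", "pocket_rmsd", "f_rms", "f_svr", "f_svc",
                    "f_tau", "f_pcf", "f_pms", "probability"))
      meta[[f[1]]] <- as.numeric(f[2])
    if (f[1] == "rotation") meta$rotation <-
        matrix(as.numeric(f[2:10]), 3, 3, byrow = TRUE)
    if (f[1] == "translation") meta$translation <- as.numeric(f[2:4])
  }
  body <- lines[!grepl("^#", lines)]
  con <- textConnection(body)
  on.exit(close(con))
  pairs <- as_tibble(utils::read.delim(con))
  tr <- structure(list(rotation = meta$rotation,
                       translation = meta$translation),
                  class = "rigid_transform")
  aln <- new_pocket_alignment(pairs, transform = tr,
                              pocket_rmsd = meta$pocket_rmsd,
                              total_cost = meta$total_cost,
                              n = meta$n, m = meta$m)
  feat <- intersect(c("f_rms", "f_svr", "f_svc", "f_tau", "f_pcf", "f_pms",
                      "probability"), names(meta))
  record <- if (length(feat)) as_tibble(meta[feat]) else NULL
  list(alignment = aln, record = record)
}

#' Write a pocket bundle as a directory of standard files
#'
#' Produces the on-disk layout consumed by [read_bundle_dir()]:
#' `structure.pdb`, `pocket.tsv`, `profile.pssm`, `ss.ss2`,
#' `templates.sdf` and (when present) `bound.sdf`. Side-chain centroids are
#' materialised as a `CG` pseudo-atom so the geometry round-trips.
#'
#' @param bundle A `pocket_bundle`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_pocket_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- bundle$pocket
  r <- p$residues
  n <- nrow(r)

  # structure: CA always; CB unless glycine; CG pseudo-atom at the
  # side-chain centroid unless glycine/alanine
  rows <- list()
  for (k in seq_len(n)) {
    aa <- r$aa[k]
    rows[[length(rows) + 1]] <- c("CA", r$ca_x[k], r$ca_y[k], r$ca_z[k], k)
    if (aa != "G" && is.finite(r$cb_x[k]))
      rows[[length(rows) + 1]] <- c("CB", r$cb_x[k], r$cb_y[k], r$cb_z[k], k)
    if (!aa %in% c("G", "A") && is.finite(r$sc_x[k]))
      rows[[length(rows) + 1]] <- c("CG", r$sc_x[k], r$sc_y[k], r$sc_z[k], k)
  }
  m <- do.call(rbind, rows)
  ridx <- as.integer(m[, 5])
  bio3d::write.pdb(file = file.path(dir, "structure.pdb"),
                   xyz = as.numeric(t(m[, 2:4])),
                   type = rep("ATOM", nrow(m)),
                   resno = r$resseq[ridx],
                   chain = r$chain[ridx],
                   insert = ifelse(r$icode[ridx] == "", "", r$icode[ridx]),
                   resid = bio3d::aa123(r$aa[ridx]),
                   elety = m[, 1],
                   eleno = seq_len(nrow(m)))

  con <- file(file.path(dir, "pocket.tsv"), "w")
  writeLines(c("# pocketalign pocket v1",
               paste0("# center\t", paste(sprintf("%.6f", p$center),
                                          collapse = "\t")),
               paste0("# props\t", paste(sprintf("%.6f", p$props),
                                         collapse = "\t")),
               "chain\tresseq\ticode\taa\tbinding_prob"), con)
  writeLines(sprintf("%s\t%d\t%s\t%s\t%.6f", r$chain, r$resseq, r$icode,
                     r$aa, r$binding_prob), con)
  close(con)

  pm <- pocket_profile_matrix(p)
  con <- file(file.path(dir, "profile.pssm"), "w")
  writeLines(paste(c("pos", "aa", AA20), collapse = "\t"), con)
  writeLines(paste(paste0(r$chain, ":", r$resseq, r$icode), r$aa,
                   apply(pm, 1, function(v)
                     paste(sprintf("%.6f", v), collapse = "\t")),
                   sep = "\t"), con)
  close(con)

  con <- file(file.path(dir, "ss.ss2"), "w")
  writeLines("pos\taa\tss\tcoil\thelix\textended", con)
  st <- c("C", "H", "E")[max.col(cbind(r$ss_c, r$ss_h, r$ss_e))]
  writeLines(sprintf("%s\t%s\t%s\t%.4f\t%.4f\t%.4f",
                     paste0(r$chain, ":", r$resseq, r$icode), r$aa, st,
                     r$ss_c, r$ss_h, r$ss_e), con)
  close(con)

  write_ligand_sdf(bundle$template_ligands, file.path(dir, "templates.sdf"))
  if (!is.null(bundle$bound_ligand))
    write_ligand_sdf(bundle$bound_ligand, file.path(dir, "bound.sdf"))
  invisible(dir)
}

#' Read a pocket bundle directory written by [write_pocket_bundle()]
#'
#' @param dir Bundle directory.
#' @return A `pocket_bundle`.
#' @export
read_bundle_dir <- function(dir) {
  bound <- file.path(dir, "bound.sdf")
  read_pocket_bundle(file.path(dir, "structure.pdb"),
                     file.path(dir, "pocket.tsv"),
                     file.path(dir, "profile.pssm"),
                     file.path(dir, "ss.ss2"),
                     file.path(dir, "templates.sdf"),
                     bound_ligand_path = if (file.exists(bound)) bound)
}
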