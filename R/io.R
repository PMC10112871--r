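#' Construct a protein alignment
#'
#' A `protein_alignment` is a character matrix of single upper-case
#' residues (20-letter alphabet plus `-` for gaps), rows = sequences
#' (unique names), columns = alignment sites. Ambiguity code `X` is
#' accepted and treated as missing data in likelihood computations.
#'
#' @param x Named character vector of aligned sequences, or a character
#'   matrix with row names.
#' @return A `protein_alignment`.
#' @export
protein_alignment <- function(x) {
  if (is.character(x) && !is.matrix(x)) {
    if (is.null(names(x)) || anyDuplicated(names(x))) {
      abort("Sequences must carry unique names.")
    }
    lens <- nchar(x)
    if (length(unique(lens)) != 1) {
      bad <- names(x)[lens != max(lens)]
      abort(paste0("Alignment rows differ in length; offending ids: ",
                   paste(bad, collapse = ", ")))
    }
    x <- do.call(rbind, strsplit(x, ""))
    rownames(x) <- names(lens)
  }
  stopifnot(is.matrix(x), is.character(x))
  if (is.null(rownames(x)) || anyDuplicated(rownames(x))) {
    abort("Alignment must have unique row names.")
  }
  x[] <- toupper(x)
  x[x %in% c(".", "*")] <- "-"
  bad <- !(x %in% c(AA_ALPHABET, "-", "X"))
  if (any(bad)) {
    ids <- unique(rownames(x)[row(x)[bad]])
    abort(paste0("Unknown residue characters in: ",
                 paste(ids, collapse = ", ")))
  }
  structure(x, class = "protein_alignment")
}

#' @export
print.protein_alignment <- function(x, ...) {
  cat("Protein alignment:", nrow(x), "sequences x", ncol(x), "sites\n")
  invisible(x)
}

#' Read an aligned protein FASTA file
#'
#' @param path Path to an aligned FASTA file of amino-acid sequences.
#' @return A [protein_alignment()].
#' @export
read_alignment <- function(path) {
  aa <- ape::read.FASTA(path, type = "AA")
  seqs <- vapply(as.character(aa), function(ch) paste(ch, collapse = ""),
                 character(1))
  protein_alignment(seqs)
}

#' Write a protein alignment as FASTA
#'
#' @param alignment A [protein_alignment()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(alignment, path) {
  stopifnot(inherits(alignment, "protein_alignment"))
  lines <- character(2 * nrow(alignment))
  lines[c(TRUE, FALSE)] <- paste0(">", rownames(alignment))
  lines[c(FALSE, TRUE)] <- apply(unclass(alignment), 1, paste, collapse = "")
  writeLines(lines, path)
  invisible(path)
}

#' Construct a labelled phylogeny
#'
#' Couples a rooted `ape::phylo` tree with per-tip activity labels
#' (nocturnal/diurnal) and named diurnal clades. Branch activity is
#' derived: a branch is diurnal if and only if it lies inside a tagged
#' diurnal clade (including the clade's stem branch). Each clade must be
#' monophyletic and consist of diurnal tips only.
#'
#' @param tree A rooted `phylo` object; branch lengths may be absent.
#' @param activity Named character vector mapping every tip to
#'   `"nocturnal"` or `"diurnal"`.
#' @param clades Named list of character vectors: clade tag (e.g. "D1")
#'   to member tip labels. Every diurnal tip must belong to exactly one
#'   clade.
#' @return An object of class `"labeled_phylogeny"`.
#' @export
labeled_phylogeny <- function(tree, activity, clades) {
  stopifnot(inherits(tree, "phylo"))
  if (!ape::is.rooted(tree)) abort("Tree must be rooted.")
  tips <- tree$tip.label
  missing <- setdiff(tips, names(activity))
  if (length(missing) > 0) {
    abort(paste0("Tips missing from activity labels: ",
                 paste(missing, collapse = ", ")))
  }
  activity <- activity[tips]
  if (!all(activity %in% c("nocturnal", "diurnal"))) {
    abort("Activity labels must be 'nocturnal' or 'diurnal'.")
  }
  clade_tips <- unlist(clades, use.names = FALSE)
  unknown <- setdiff(clade_tips, tips)
  if (length(unknown) > 0) {
    abort(paste0("Clade members not in tree: ", paste(unknown, collapse = ", ")))
  }
  diurnal_tips <- tips[activity == "diurnal"]
  stray <- setdiff(diurnal_tips, clade_tips)
  if (length(stray) > 0) {
    abort(paste0("Diurnal tip(s) outside any tagged clade: ",
                 paste(stray, collapse = ", ")))
  }
  for (tag in names(clades)) {
    members <- clades[[tag]]
    if (any(activity[members] != "diurnal")) {
      abort(paste0("Clade ", tag, " contains non-diurnal tips."))
    }
    if (length(members) > 1) {
      mrca <- ape::getMRCA(tree, members)
      desc <- tips[descendant_tips(tree, mrca)]
      if (!setequal(desc, members)) {
        abort(paste0("Clade ", tag, " is not monophyletic."))
      }
    }
  }
  structure(list(tree = tree, activity = activity, clades = clades),
            class = "labeled_phylogeny")
}

# indices of tips descending from (or equal to) a node
descendant_tips <- function(tree, node) {
  n_tip <- length(tree$tip.label)
  if (node <= n_tip) return(node)
  out <- integer(0)
  stack <- node
  while (length(stack) > 0) {
    v <- stack[1]; stack <- stack[-1]
    kids <- tree$edge[tree$edge[, 1] == v, 2]
    out <- c(out, kids[kids <= n_tip])
    stack <- c(stack, kids[kids > n_tip])
  }
  sort(out)
}

#' @export
print.labeled_phylogeny <- function(x, ...) {
  cat("Labelled phylogeny:", length(x$tree$tip.label), "tips;",
      sum(x$activity == "diurnal"), "diurnal in",
      length(x$clades), "clade(s):",
      paste(names(x$clades), collapse = ", "), "\n")
  invisible(x)
}

#' Read a labelled tree from Newick + YAML label files
#'
#' The YAML file carries two maps: `activity` (tip label to
#' nocturnal/diurnal) and `clades` (clade tag to list of member tips).
#'
#' @param newick_path Path to a rooted Newick tree.
#' @param labels_path Path to the YAML label file.
#' @return A [labeled_phylogeny()].
#' @export
read_labeled_tree <- function(newick_path, labels_path) {
  tree <- ape::read.tree(newick_path)
  if (is.null(tree)) abort("Could not parse Newick file.")
  labels <- yaml::read_yaml(labels_path)
  if (!all(c("activity", "clades") %in% names(labels))) {
    abort("Labels YAML must contain 'activity' and 'clades' maps.")
  }
  labeled_phylogeny(tree, unlist(labels$activity),
                    lapply(labels$clades, unlist))
}

#' The hawkmoth species-tree fixture
#'
#' A rooted species tree for ten hawkmoth species plus *Manduca sexta*,
#' *Macroglossum stellatarum* and the outgroup *Helicoverpa armigera*,
#' following published hawkmoth phylogenies, with *M. stellatarum* placed
#' next to *M. bombylans* as in the opsin gene trees. Three independently
#' evolved diurnal clades are tagged: D1 (*Cephonodes hylas*, *Hemaris
#' affinis*), D2 (*Neogurelca himachala*) and D3 (*Macroglossum
#' pyrrhosticta*, *M. bombylans*, *M. stellatarum*). Branch lengths are
#' nominal amino-acid distances supplied for simulation work, not
#' estimates from data.
#'
#' @return A [labeled_phylogeny()].
#' @examples
#' tr <- hawkmoth_tree()
#' lengths(tr$clades)
#' @export
hawkmoth_tree <- function() {
  read_labeled_tree(
    system.file("extdata", "hawkmoth_tree.nwk", package = "opsinshift",
                mustWork = TRUE),
    system.file("extdata", "hawkmoth_labels.yml", package = "opsinshift",
                mustWork = TRUE))
}

#' Read / write ERG tables and sensitivity curves
#'
#' Thin CSV readers/writers for the tabular interchange formats: long ERG
#' spectral responses (`species, individual, series, direction,
#' wavelength_nm, response_mv`), V-log I series (`species, individual,
#' log10_intensity, response_mv`) and sensitivity curves
#' (`wavelength_nm, s, sem`).
#'
#' @param path File path.
#' @param data Tibble to write.
#' @return A tibble (readers) or `path` invisibly (writer).
#' @name erg_io
NULL

#' @rdname erg_io
#' @export
read_erg_csv <- function(path) {
  as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname erg_io
#' @export
write_erg_csv <- function(data, path) {
  utils::write.csv(data, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname erg_io
#' @export
read_sensitivity_csv <- function(path) {
  d <- as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
  stopifnot(all(c("wavelength_nm", "s") %in% names(d)))
  d
}
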