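.db_cache <- new.env(parent = emptyenv())

#' Load the lipid reaction database
#'
#' Reads the packaged (or a user-supplied) reaction database: the subclass
#' registry, the directed reaction table and the named pathway subsets. The
#' packaged database covers the mammalian glycerophospholipid, glycerolipid,
#' sphingolipid and fatty-acid elongation/desaturation networks: 94 reactions
#' over 41 subclasses, each reaction annotated with human (HGNC) gene
#' symbols. Fatty-acid steps are composition-specific entries (e.g.
#' \code{FA(22:5)->FA(24:5)}, an ELOVL2 elongation).
#'
#' The tables are validated on load: unique reaction ids, substrate and
#' product codes present in the registry, no self-loops, non-empty gene
#' lists, balance-consistent fatty-acid steps (+2 carbons for elongation,
#' +1 double bond for desaturation), and subset members that exist in the
#' reaction table. A violation raises an error naming the offending record.
#'
#' @param path directory containing \code{subclasses.tsv},
#'   \code{reactions.tsv} and \code{subsets.tsv} in the packaged schema, or
#'   \code{NULL} for the packaged database.
#' @return an object of class \code{reaction_db}: list with data.frames
#'   \code{subclasses} (code, category, name), \code{reactions} (id,
#'   substrate, product, sub_comp, prod_comp, kind, genes list-column) and
#'   \code{subsets} (subset, reaction_id).
#' @examples
#' db <- load_reaction_db()
#' nrow(db$reactions)   # 94
#' nrow(db$subclasses)  # 41
#' @export
load_reaction_db <- function(path = NULL) {
  if (is.null(path)) {
    if (!is.null(.db_cache$default)) return(.db_cache$default)
    dir <- system.file("extdata", package = "lipidpath")
  } else {
    dir <- path
  }
  read_tsv <- function(f) {
    fp <- file.path(dir, f)
    if (!file.exists(fp)) stop("database file not found: ", fp)
    out <- utils::read.delim(fp, sep = "\t", stringsAsFactors = FALSE,
                             colClasses = "character")
    if (!nrow(out)) stop("database file is empty: ", fp)
    out
  }
  subclasses <- read_tsv("subclasses.tsv")
  reactions <- read_tsv("reactions.tsv")
  subsets <- read_tsv("subsets.tsv")

  needed <- c("id", "substrate", "product", "sub_comp", "prod_comp", "kind", "genes")
  if (!all(needed %in% names(reactions))) {
    stop("reactions table must have columns: ", paste(needed, collapse = ", "))
  }
  if (anyDuplicated(reactions$id)) {
    stop("duplicate reaction id: ",
         reactions$id[duplicated(reactions$id)][1])
  }
  if (anyDuplicated(subclasses$code)) {
    stop("duplicate subclass code: ",
         subclasses$code[duplicated(subclasses$code)][1])
  }
  kinds <- c("headgroup_transfer", "acylation", "deacylation",
             "fa_elongation", "fa_desaturation", "sphingoid_step")
  for (i in seq_len(nrow(reactions))) {
    r <- reactions[i, ]
    if (!(r$substrate %in% subclasses$code))
      stop("reaction ", r$id, ": unknown substrate subclass ", r$substrate)
    if (!(r$product %in% subclasses$code))
      stop("reaction ", r$id, ": unknown product subclass ", r$product)
    if (!(r$kind %in% kinds))
      stop("reaction ", r$id, ": unknown kind ", r$kind)
    if (!nzchar(r$genes))
      stop("reaction ", r$id, ": empty gene list")
    is_fa_kind <- r$kind %in% c("fa_elongation", "fa_desaturation")
    if (is_fa_kind) {
      sc <- parse_comp(r$sub_comp); pc <- parse_comp(r$prod_comp)
      if (is.null(sc) || is.null(pc))
        stop("reaction ", r$id, ": fatty-acid step needs sub_comp/prod_comp")
      if (r$kind == "fa_elongation" &&
          !(pc$carbons == sc$carbons + 2L && pc$double_bonds == sc$double_bonds))
        stop("reaction ", r$id, ": elongation must add two carbons")
      if (r$kind == "fa_desaturation" &&
          !(pc$carbons == sc$carbons && pc$double_bonds == sc$double_bonds + 1L))
        stop("reaction ", r$id, ": desaturation must add one double bond")
    } else {
      if (r$substrate == r$product)
        stop("reaction ", r$id, ": self-loop")
    }
  }
  bad <- setdiff(subsets$reaction_id, reactions$id)
  if (length(bad)) stop("subset references unknown reaction: ", bad[1])

  reactions$genes <- strsplit(reactions$genes, ";", fixed = TRUE)
  db <- structure(list(subclasses = subclasses, reactions = reactions,
                       subsets = subsets),
                  class = "reaction_db")
  if (is.null(path)) .db_cache$default <- db
  db
}

# "16:0" -> list(carbons, double_bonds); NULL if empty/invalid
parse_comp <- function(x) {
  if (is.na(x) || !nzchar(x)) return(NULL)
  m <- regmatches(x, regexec("^([0-9]+):([0-9]+)$", x))[[1]]
  if (!length(m)) return(NULL)
  list(carbons = as.integer(m[2]), double_bonds = as.integer(m[3]))
}

# node label of a reaction endpoint: subclass code, or "FA(22:5)" for
# composition-specific fatty-acid steps
reaction_node <- function(r, side = c("substrate", "product")) {
  side <- match.arg(side)
  comp <- if (side == "substrate") r$sub_comp else r$prod_comp
  code <- r[[side]]
  pc <- parse_comp(comp)
  if (is.null(pc)) code else make_label(code, pc$carbons, pc$double_bonds)
}

# locate the reaction row for a substrate -> product node pair (codes or
# FA(C:D) labels); NULL when absent
find_reaction <- function(db, substrate, product) {
  rx <- db$reactions
  for (i in seq_len(nrow(rx))) {
    if (identical(reaction_node(rx[i, ], "substrate"), substrate) &&
        identical(reaction_node(rx[i, ], "product"), product)) {
      return(rx[i, ])
    }
  }
  NULL
}

#' Gene symbols annotated to a single reaction
#'
#' @param db a \code{reaction_db}.
#' @param substrate,product subclass codes (e.g. \code{"PE"}, \code{"PC"}),
#'   or \code{"FA(C:D)"} labels for fatty-acid steps
#'   (e.g. \code{"FA(22:5)"}, \code{"FA(24:5)"}).
#' @return ordered, de-duplicated character vector of HGNC gene symbols.
#' @examples
#' db <- load_reaction_db()
#' genes_for(db, "PE", "PC")                  # PEMT
#' genes_for(db, "FA(22:5)", "FA(24:5)")      # ELOVL2
#' @export
genes_for <- function(db, substrate, product) {
  r <- find_reaction(db, substrate, product)
  if (is.null(r)) {
    stop("no reaction ", substrate, " -> ", product, " in the database")
  }
  unique(r$genes[[1]])
}

#' Genes predicted along a reaction chain
#'
#' Concatenates the per-step gene lists of a chain of consecutive reactions,
#' de-duplicated preserving first occurrence. The chain is given as the
#' ordered vector of its node labels, so a k-step chain has k+1 labels.
#'
#' @param db a \code{reaction_db}.
#' @param nodes character vector of node labels along the chain, e.g.
#'   \code{c("PE", "PC", "PS", "LPS")}. Vectors of length < 2 give an empty
#'   chain.
#' @return character vector of gene symbols; \code{character(0)} for an
#'   empty chain.
#' @examples
#' db <- load_reaction_db()
#' chain_genes(db, c("PE", "PC", "PS", "LPS"))
#' @export
chain_genes <- function(db, nodes) {
  if (length(nodes) < 2L) return(character(0))
  genes <- character(0)
  for (i in seq_len(length(nodes) - 1L)) {
    genes <- c(genes, genes_for(db, nodes[i], nodes[i + 1L]))
  }
  unique(genes)
}

#' @export
print.reaction_db <- function(x, ...) {
  cat(sprintf("<reaction_db> %d reactions over %d subclasses; %d named subsets\n",
              nrow(x$reactions), nrow(x$subclasses),
              length(unique(x$subsets$subset))))
  invisible(x)
}
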