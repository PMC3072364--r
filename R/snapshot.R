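## Tissue snapshot format: a documented JSON document with arrays
##   vertices: [id, x, y]
##   edges:    [id, v1, v2, c1, c2, margin]   (c2 = null on margin edges)
##   cells:    [id, vertex cycle, compartment, genotype, clone_id,
##              concentrations (7 floats), target_area]
## Floats are written at full precision so a write/read round trip is
## bit-exact.

#' Write a tissue snapshot to JSON
#'
#' @param tissue a `tissue`.
#' @param path output file path.
#' @return Invisibly `path`.
#' @export
write_tissue <- function(tissue, path) {
  ed <- tissue_edges(tissue)
  doc <- list(
    format = "wingvertex-tissue",
    version = 1L,
    vertices = cbind(id = seq_len(nrow(tissue$xy)),
                     x = tissue$xy[, 1L], y = tissue$xy[, 2L]),
    edges = data.frame(id = seq_len(nrow(ed)), v1 = ed$v1, v2 = ed$v2,
                       c1 = ed$c1, c2 = ed$c2, margin = ed$margin),
    cells = lapply(seq_len(n_cells(tissue)), function(i) {
      list(id = i,
           vertices = tissue$cells[[i]],
           compartment = comp_names[tissue$compartment[i]],
           genotype = geno_names[tissue$genotype[i] + 1L],
           clone_id = tissue$clone_id[i],
           concentrations = unname(tissue$conc[i, ]),
           target_area = tissue$target_area[i])
    })
  )
  ## I(17): 17 significant digits, enough to reproduce any double exactly
  jsonlite::write_json(doc, path, digits = I(17), auto_unbox = TRUE,
                       na = "null", pretty = FALSE)
  invisible(path)
}

#' Read a tissue snapshot written by [write_tissue()]
#'
#' @param path JSON file path.
#' @return A `tissue`.
#' @export
read_tissue <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  if (!identical(doc$format, "wingvertex-tissue")) {
    stop("not a wingvertex tissue snapshot: ", path)
  }
  verts <- doc$vertices
  xy <- matrix(0, nrow(verts), 2L)
  xy[verts[, 1L], ] <- verts[, 2:3]
  cells <- lapply(doc$cells, function(cl) as.integer(cl$vertices))
  ids <- vapply(doc$cells, function(cl) cl$id, numeric(1))
  o <- order(ids)
  getf <- function(f, cast) cast(vapply(doc$cells, f, numeric(1))[o])
  tissue <- new_tissue(
    xy,
    cells[o],
    compartment = match(vapply(doc$cells, function(cl) cl$compartment,
                               character(1))[o], comp_names),
    genotype = match(vapply(doc$cells, function(cl) cl$genotype,
                            character(1))[o], geno_names) - 1L,
    clone_id = vapply(doc$cells, function(cl) {
      if (is.null(cl$clone_id)) NA_integer_ else as.integer(cl$clone_id)
    }, integer(1))[o],
    conc = do.call(rbind, lapply(doc$cells, function(cl) {
      as.numeric(cl$concentrations)
    }))[o, , drop = FALSE],
    target_area = vapply(doc$cells, function(cl) as.numeric(cl$target_area),
                         numeric(1))[o]
  )
  tissue
}
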