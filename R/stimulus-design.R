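#' The default 48-stimulus object design
#'
#' Constructs the stimulus design used throughout the package: 48 stimuli,
#' eight exemplars in each of six object groupings -- graspable food items
#' (`FoodItem`), food-preparation tools (`FoodTool`), tools for actions on
#' other objects (`OtherTool`), tools for self-directed action (`SelfTool`),
#' manipulable non-tool artefacts (`ManipulableObject`), and animals
#' (`Animal`). Within each grouping the shape profile is counterbalanced:
#' four exemplars with a high (elongated) and four with a low (stubby)
#' aspect ratio.
#'
#' Ordering is fixed as type-major, aspect-ratio-minor (high before low),
#' which makes every matrix serialization of the design reproducible.
#'
#' @return A data frame of class `stimulus_design` with columns
#'   `stimulus_id`, `object_type` (factor with 6 levels), `aspect_ratio`
#'   (`"high"`/`"low"`), and `display_label`.
#' @examples
#' d <- build_default_design()
#' table(d$object_type, d$aspect_ratio)
#' @export
build_default_design <- function() {
  types <- object_type_levels()
  rows <- do.call(rbind, lapply(types, function(ty) {
    ar <- rep(c("high", "low"), each = 4)
    idx <- seq_len(8)
    data.frame(
      stimulus_id = sprintf("%s_%s%d", tolower(ty), substr(ar, 1, 1),
                            c(1:4, 1:4)),
      object_type = ty,
      aspect_ratio = ar,
      display_label = sprintf("%s exemplar %d (%s aspect ratio)", ty, idx, ar),
      stringsAsFactors = FALSE
    )
  }))
  rows$object_type <- factor(rows$object_type, levels = types)
  validate_design(rows)
  class(rows) <- c("stimulus_design", "data.frame")
  rows
}

object_type_levels <- function() {
  c("FoodItem", "FoodTool", "OtherTool", "SelfTool",
    "ManipulableObject", "Animal")
}

## Superclass of an object type: food, artefact (the four manipulable
## artefact groupings), or animal.
object_superclass <- function(type) {
  type <- as.character(type)
  out <- rep(NA_character_, length(type))
  out[type == "FoodItem"] <- "Food"
  out[type %in% c("FoodTool", "OtherTool", "SelfTool",
                  "ManipulableObject")] <- "Artefact"
  out[type == "Animal"] <- "Animal"
  if (anyNA(out)) {
    stop("unknown object type(s): ",
         paste(unique(type[is.na(out)]), collapse = ", "))
  }
  out
}

validate_design <- function(design) {
  stopifnot(is.data.frame(design))
  need <- c("stimulus_id", "object_type", "aspect_ratio")
  if (!all(need %in% names(design))) {
    stop("design needs columns: ", paste(need, collapse = ", "))
  }
  if (anyDuplicated(design$stimulus_id)) stop("stimulus_ids must be unique")
  if (!all(design$aspect_ratio %in% c("high", "low"))) {
    stop("aspect_ratio must be 'high' or 'low'")
  }
  invisible(design)
}

#' Dummy-coded object-type model RDM
#'
#' Builds the object-type predictor RDM from a stimulus design by assigning
#' a dissimilarity level to every pair of superclasses (Food, Artefact,
#' Animal). The default coding places food items intermediate between
#' artefacts and animals: pairs within a superclass get 0, food-artefact
#' pairs 1, and any pair involving an animal 2. Only the rank order of the
#' levels matters for Spearman-based RSA, so any order-preserving relabeling
#' of the coding yields identical model comparisons.
#'
#' @param design A `stimulus_design` data frame (see
#'   [build_default_design()]).
#' @param coding Named numeric vector of dissimilarity levels for the
#'   unordered superclass pairs `Food.Artefact`, `Food.Animal`,
#'   `Artefact.Animal`, and optionally `within` (default 0).
#' @return A model [rdm] with as many distinct off-diagonal values as the
#'   coding defines.
#' @export
make_type_model_rdm <- function(design,
                                coding = c(within = 0,
                                           Food.Artefact = 1,
                                           Food.Animal = 2,
                                           Artefact.Animal = 2)) {
  validate_design(design)
  sup <- object_superclass(design$object_type)
  need <- c("within", "Food.Artefact", "Food.Animal", "Artefact.Animal")
  if (!all(need %in% names(coding))) {
    stop("coding must name: ", paste(need, collapse = ", "))
  }
  n <- nrow(design)
  pair_level <- function(s1, s2) {
    if (s1 == s2) return(coding[["within"]])
    key <- paste(sort(c(s1, s2)), collapse = ".")
    key <- switch(key,
                  "Artefact.Food" = "Food.Artefact",
                  "Animal.Food" = "Food.Animal",
                  "Animal.Artefact" = "Artefact.Animal",
                  key)
    coding[[key]]
  }
  m <- outer(seq_len(n), seq_len(n),
             Vectorize(function(i, j) pair_level(sup[i], sup[j])))
  rdm(m, ids = design$stimulus_id, source = "model",
      distance_name = "object-type dummy coding")
}

#' Binary shape (aspect-ratio) model RDM
#'
#' Dissimilarity 0 for stimulus pairs sharing the same aspect-ratio label
#' (both elongated or both stubby) and 1 otherwise.
#'
#' @inheritParams make_type_model_rdm
#' @return A binary model [rdm].
#' @export
make_shape_model_rdm <- function(design) {
  validate_design(design)
  if (anyNA(design$aspect_ratio)) stop("missing aspect_ratio label(s)")
  ar <- design$aspect_ratio
  m <- outer(ar, ar, FUN = function(a, b) as.numeric(a != b))
  rdm(m, ids = design$stimulus_id, source = "model",
      distance_name = "aspect-ratio binary coding")
}

#' Write / read a stimulus design as TSV
#'
#' @param design A `stimulus_design` data frame.
#' @param path File path.
#' @return `read_design` returns the design; `write_design` returns `path`
#'   invisibly.
#' @export
write_design <- function(design, path) {
  validate_design(design)
  utils::write.table(design, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_design
#' @export
read_design <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  d$object_type <- factor(d$object_type, levels = object_type_levels())
  validate_design(d)
  class(d) <- c("stimulus_design", "data.frame")
  d
}
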