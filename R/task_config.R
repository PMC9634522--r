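#' Task constraint configuration
#'
#' A task configuration declares the entity types, relation categories and the
#' legal (type, type, category) triples of a relation-extraction task. Pairs
#' are unordered: the tasks supported here do not distinguish argument
#' direction, so a triple (A, B, cat) also licenses (B, A, cat). The reserved
#' label `"none"` (non-relation) is always appended as the final category.
#'
#' @param name task name, e.g. `"bbrel"`.
#' @param entity_types character vector of entity-type names.
#' @param categories list of category descriptors; each a list with elements
#'   `name`, `roles` (length-2 character, argument role names used when
#'   writing `.a2` lines) and `pairs` (list of length-2 type pairs; the type
#'   `"*"` matches any entity type).
#' @param type_priority character vector of entity types that must appear
#'   first on an oriented dependency path (may be empty).
#' @return an object of class `task_config`.
#' @seealso [bbrel_task()], [seedev_task()], [read_task_config()]
#' @export
task_config <- function(name, entity_types, categories, type_priority = character()) {
  stopifnot(is.character(name), length(name) == 1L, is.character(entity_types))
  cat_names <- vapply(categories, function(x) x$name, character(1))
  if (anyDuplicated(cat_names)) stopf("duplicate relation categories in task '%s'", name)
  if ("none" %in% cat_names) stopf("'none' is reserved; do not declare it as a category")
  for (cc in categories) {
    if (length(cc$roles) != 2L) stopf("category '%s': need exactly 2 role names", cc$name)
  }
  structure(
    list(
      name = name,
      entity_types = entity_types,
      categories = categories,
      category_names = c(cat_names, "none"),
      type_priority = type_priority
    ),
    class = "task_config"
  )
}

#' @export
print.task_config <- function(x, ...) {
  cat(sprintf("<task_config '%s': %d entity types, %d relation categories + none>\n",
              x$name, length(x$entity_types), length(x$categories)))
  invisible(x)
}

#' Relation categories legal for an unordered entity-type pair
#'
#' @param rules a [task_config()].
#' @param type_a,type_b entity-type names.
#' @return character vector of category names (possibly empty), never "none".
#' @export
legal_categories <- function(rules, type_a, type_b) {
  stopifnot(inherits(rules, "task_config"))
  out <- character()
  for (cc in rules$categories) {
    for (p in cc$pairs) {
      hit <- (match_type(p[1], type_a) && match_type(p[2], type_b)) ||
             (match_type(p[1], type_b) && match_type(p[2], type_a))
      if (hit) { out <- c(out, cc$name); break }
    }
  }
  out
}

match_type <- function(pattern, type) pattern == "*" || pattern == type

#' Read a task configuration from YAML
#'
#' The YAML schema mirrors the [task_config()] arguments; see
#' `system.file("extdata", "bbrel.yaml", package = "biorel")` for a complete
#' example.
#'
#' @param path path to a YAML file.
#' @return a [task_config()].
#' @export
read_task_config <- function(path) {
  y <- yaml::read_yaml(path)
  for (k in c("name", "entity_types", "categories")) {
    if (is.null(y[[k]])) stopf("task config %s: missing key '%s'", path, k)
  }
  task_config(
    name = y$name,
    entity_types = unlist(y$entity_types),
    categories = lapply(y$categories, function(cc) {
      list(name = cc$name, roles = unlist(cc$roles),
           pairs = lapply(cc$pairs, unlist))
    }),
    type_priority = unlist(y$type_priority) %||% character()
  )
}

#' Built-in Bacteria-Biotope relation task configuration
#'
#' Encodes the type-constraint rules of the Bacteria-Biotope relation task:
#' `Lives_In` links a Microorganism to a Habitat or Geographical entity,
#' `Exhibits` links a Microorganism to a Phenotype entity; all other type
#' pairs (e.g. Geographical with Phenotype) carry no relation and generate no
#' candidate instances. Dependency paths are oriented Microorganism-first.
#'
#' @return a [task_config()].
#' @export
bbrel_task <- function() {
  read_task_config(system.file("extdata", "bbrel.yaml", package = "biorel"))
}

#' Seed-development binary relation task configuration
#'
#' The 22 relation categories and entity types of the plant seed-development
#' binary task. The official legal-triple table is not part of this package's
#' sources: the shipped YAML licenses every type pair for every category
#' (wildcard pairs) and is intended to be edited down from the task
#' documentation. The cluster mapping used by [cluster_report()] ships
#' alongside it (`seedev_clusters.yaml`) and is equally editable.
#'
#' @return a [task_config()].
#' @export
seedev_task <- function() {
  read_task_config(system.file("extdata", "seedev.yaml", package = "biorel"))
}
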