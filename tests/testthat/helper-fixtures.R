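# Shared fixtures, all built in code.

# Structure-based names printed for the study's key compounds: simple
# ascarosides, DASC homologous series, head-group monomers and dimers.
reported_names <- c(
  "asc-\u03c9C3",                 # ascr#5
  "asc-C4",                       # ascr#11
  "asc-C5",                       # ascr#9
  "asc-C6",                       # ascr#12
  "asc-C7",                       # ascr#1
  "asc-\u0394C7",                 # ascr#7
  "asc-C8",                       # ascr#14
  "asc-C9",                       # ascr#10
  "asc-C11",                      # ascr#18
  "4'-(asc-C7)-asc-C7",           # dasc#1
  "2'-(asc-C5)-asc-C4",           # dasc#3
  "2'-(asc-C5)-asc-C5",           # dasc#4
  "4'-(asc-C5)-asc-C5",           # dasc#5
  "2'-(asc-C6)-asc-C5",           # dasc#6
  "2'-(asc-C7)-asc-C5",           # dasc#9
  "4'-(asc-C5)-asc-C7",           # dasc#10
  "4'-(asc-C6)-asc-C7",           # dasc#12
  "4'-(asc-\u0394C7)-asc-C5",     # dasc#14
  "4'-(asc-\u0394C7)-asc-C6",     # dasc#15
  "4'-(asc-\u0394C7)-asc-C7",     # dasc#16
  "4'-(asc-\u0394C7)-asc-\u0394C7", # dasc#17
  "4'-UB-asc-C5",                 # ubas#3
  "4'-UB-asc-C4",                 # ubas#5
  "4'-UB-2'-(asc-C5)-asc-C5",     # ubas#30
  "4'-UB-2'-(asc-C4)-asc-C4",     # ubas#34
  "4'-UB-2'-(asc-C5)-asc-C4",     # ubas#28
  "4'-UP-2'-(asc-C4)-asc-C4",     # upas#34
  "4'-UP-2'-(asc-C5)-asc-C4",     # upas#28
  "4'-UP-asc-C4"                  # upas#5
)

# small long-format replicate table with two UBAS sub-classes
make_test_areas <- function() {
  compounds <- c("dasc#1", "dasc#4", "ubas#1", "ubas#28", "ascr#1")
  classes <- c("DASC", "DASC", "UBAS-monomeric", "UBAS-dimeric", "simple")
  areas <- tidyr::expand_grid(
    species = c("sp1", "sp2", "sp3"),
    compound = compounds,
    replicate = 1:3
  )
  set.seed(99)
  areas$area <- round(stats::runif(nrow(areas), 0, 5e3))
  # plant structure: sp3 lacks all DASC
  areas$area[areas$species == "sp3" & areas$compound %in%
               c("dasc#1", "dasc#4")] <- 0
  list(areas = areas,
       class_map = tibble::tibble(compound = compounds, class = classes))
}

# caterpillar ((A:1,B:2):3,C:4); patristic: AB=3, AC=8, BC=9
caterpillar3 <- function() {
  ape::read.tree(text = "((A:1,B:2):3,C:4);")
}
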