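# Small CSV fixtures built in code at test time.

write_fixture <- function(lines, name) {
  path <- file.path(withr::local_tempdir(.local_envir = parent.frame()),
                    name)
  writeLines(lines, path)
  path
}

quantal_csv_lines <- c(
  "label,axis,value,n_exposed,n_dead,time_hr",
  "TGA,dose,400,10,9,72",
  "TGA,dose,100,10,2,72",
  "TGA,dose,100,10,3,72",
  "TGA,dose,50,20,0,72",
  "TGA,dose,200,20,12,72",
  "TGA 300 nM,time,24,20,4,",
  "TGA 300 nM,time,12,20,0,",
  "TGA 300 nM,time,48,20,15,",
  "TGA 300 nM,time,72,20,20,"
)

scores_csv_lines <- function() {
  set.seed(7)
  doses <- c(50, 100, 200, 400)
  times <- c(24, 48, 72)
  rows <- "animal_id,label,dose_nM,time_hr,score"
  for (t in times) for (d in doses) for (a in 1:5) {
    base <- round(10 - 6 * (log10(d / 50) / log10(8)) * (t / 72))
    s <- min(10, max(1, base + sample(-1:1, 1)))
    rows <- c(rows, sprintf("a%d_%d,TGA,%d,%d,%d", a, d, d, t, s))
  }
  rows
}

tentacles_csv_lines <- c(
  "polyp_id,label,day,c1,c2,c3,c4,c5",
  "p1,control,0,0,0,0,0,0",
  "p1,control,7,1,2,1,0,0",
  "p1,control,14,0,0,0,0,8",
  "p2,control,0,0,0,0,0,0",
  "p2,control,7,2,1,1,0,0",
  "p2,control,14,0,0,1,2,5"
)

population_csv_lines <- c(
  "replicate_id,label,day,n",
  "r1,control,0,4",
  "r1,control,3,8",
  "r1,control,6,16",
  "r2,control,0,4",
  "r2,control,3,7",
  "r2,control,6,15"
)
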