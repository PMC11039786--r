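# Packaged word lists. The toolkit deliberately ships small static pools
# instead of scraped public dictionaries; they are large enough to exercise
# dictionary lookup, typo corruption and placeholder consistency.

.hds_first_names <- c(
  "Anna", "Maria", "Elisabeth", "Johanna", "Katharina", "Magdalena", "Sophie",
  "Theresa", "Christina", "Barbara", "Claudia", "Sabine", "Monika", "Andrea",
  "Petra", "Verena", "Julia", "Lena", "Hannah", "Laura", "Franziska", "Eva",
  "Johann", "Josef", "Franz", "Karl", "Georg", "Thomas", "Michael", "Andreas",
  "Stefan", "Markus", "Christian", "Martin", "Peter", "Wolfgang", "Herbert",
  "Werner", "Gerhard", "Helmut", "Manfred", "Friedrich", "Heinrich", "Lukas",
  "Florian", "Sebastian", "Matthias", "Tobias", "Simon", "David"
)

.hds_last_names <- c(
  "Gruber", "Huber", "Bauer", "Wagner", "Pichler", "Steiner", "Moser",
  "Mayer", "Hofer", "Leitner", "Berger", "Fuchs", "Eder", "Fischer",
  "Schmid", "Winkler", "Weber", "Schwarz", "Maier", "Schneider", "Reiter",
  "Mayr", "Schmidt", "Wimmer", "Egger", "Brunner", "Lang", "Baumgartner",
  "Auer", "Binder", "Lechner", "Wolf", "Wallner", "Aigner", "Ebner",
  "Koller", "Lehner", "Haas", "Schuster", "Müller", "Stadler", "Hofbäck",
  "König", "Böhm", "Jäger", "Schönbäck", "Grünwald", "Strauß", "Hofstätter", "Krämer"
)

# Out-of-registry "public" person names (invented) for the public dictionary.
.hds_public_names <- c(
  "Adlersfeld", "Brandtner", "Cornelius", "Dorfmeister", "Ehrenberg",
  "Falkenrath", "Gallenberg", "Hartenstein", "Immervoll", "Jorberg",
  "Kranewitter", "Lindwurm", "Morgenthal", "Nepomuk", "Ortenburg",
  "Pernlochner", "Quirinus", "Rosenstingl", "Silberbauer", "Taxenbacher"
)

# Clinician surnames kept out of every dictionary so that precursor
# promotion ("Dr. X") is the only way to recognize them.
.hds_prof_names <- c(
  "Zangerl", "Untermoser", "Veidner", "Wechselberger", "Xandler",
  "Ybbstaler", "Zillenbichler", "Achhorner", "Brixner", "Clementsch",
  "Defregger", "Ellmauer", "Feuersinger", "Gasteiger", "Hinterholzer"
)

.hds_locations <- c(
  "Innsbruck", "Hall", "Schwaz", "Kufstein", "Landeck", "Imst", "Lienz",
  "Telfs", "Wörgl", "Rum", "Zirl", "Absam", "Kitzbühel", "Reutte", "Wattens"
)

.hds_streets <- c(
  "Anichstraße", "Museumstraße", "Speckbacherstraße", "Innrain",
  "Maximilianstraße", "Salurner Straße", "Haller Straße",
  "Schidlachgasse", "Bozner Platz", "Klostergasse", "Mitterweg", "Fennerweg"
)

# Small demo formulary: brand name -> active ingredient (ATC in the demo
# vocabulary map). Used by the telehealth generator and the ETL tests.
.hds_drugs <- data.frame(
  brand = c("Lasix", "Concor", "Herzass", "Entresto", "Jardiance", "Inspra"),
  ingredient = c("furosemide", "bisoprolol", "acetylsalicylic acid",
                 "sacubitril/valsartan", "empagliflozin", "eplerenone"),
  stringsAsFactors = FALSE
)

#' Default name dictionaries
#'
#' The packaged word lists used by the note generator and by
#' [default_ruleset()]: an "internal" dictionary (names occurring in the
#' synthetic registry's identity pools), a "public" person dictionary,
#' clinician surnames (deliberately absent from both dictionaries, so they
#' are only caught via title precursors), locations and street names.
#'
#' @return named list of character vectors.
#' @export
default_dictionaries <- function() {
  list(
    internal_names = c(.hds_first_names, .hds_last_names),
    public_names = .hds_public_names,
    professional_names = .hds_prof_names,
    locations = .hds_locations,
    streets = .hds_streets
  )
}
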