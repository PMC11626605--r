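# Housing concept lexicon
# version: 1.0
# columns: concept, pattern, source_phrases (|-separated), case_sensitive, notes
# Dialect: PCRE subset; literal spaces match whitespace runs; patterns are
# word-boundary anchored at compile time.
concept	pattern	source_phrases	case_sensitive	notes
homeless	homeless(ness|s)?	homeless|homelessness|homelesss	false	canonical stem; trailing-s misspelling seen in real notes
homeless	lack of (shelter|housing)	lack of shelter|lack of housing	false	canonical pattern; compressed alternation
homeless	living on the (the)? streets?	living on the street|living on the streets	false	canonical pattern; optional repeated article, singular or plural
homeless	unhoused	unhoused	false	curated extension
homeless	undomiciled	undomiciled	false	curated extension
homeless	no fixed (address|abode)	no fixed address|no fixed abode	false	curated extension
homeless	sleeping rough	sleeping rough	false	curated extension
unstable_housing	housing (instability|insecurity)	housing instability|housing insecurity	false	curated extension
unstable_housing	(unstable|precarious|inadequate) housing	unstable housing|precarious housing|inadequate housing	false	curated extension
unstable_housing	housing (problems|issues|concerns)	housing problems|housing issues|housing concerns	false	curated extension
unstable_housing	at risk of (losing housing|eviction|homelessness)	at risk of losing housing|at risk of eviction|at risk of homelessness	false	curated extension
unstable_housing	couch surfing	couch surfing	false	curated extension
unstable_housing	facing eviction	facing eviction	false	curated extension
unstable_housing	doubled up	doubled up	false	curated extension; staying with others out of necessity
recovery_housing	recovery (housing|residence|home)	recovery housing|recovery residence|recovery home	false	curated extension
recovery_housing	sober living( house| home| facility)?	sober living|sober living house|sober living home|sober living facility	false	curated extension; optional facility word
recovery_housing	halfway house	halfway house	false	curated extension
recovery_housing	oxford house	oxford house	false	curated extension
emergency_housing	emergency (housing|shelter|accommodation)	emergency housing|emergency shelter|emergency accommodation	false	curated extension
emergency_housing	homeless shelter	homeless shelter	false	curated extension
emergency_housing	crisis housing	crisis housing	false	curated extension
emergency_housing	staying (in|at) (a |the )?shelter	staying in a shelter|staying at a shelter|staying in the shelter|staying at the shelter	false	curated extension
temporary_housing	temporary (housing|shelter|accommodation)	temporary housing|temporary shelter|temporary accommodation	false	curated extension
temporary_housing	transitional (housing|living)	transitional housing|transitional living	false	curated extension
temporary_housing	living in (a |the )?(motel|hotel|car|vehicle)	living in a motel|living in a hotel|living in a car|living in the car|living in a vehicle	false	curated extension
temporary_housing	staying with (friends|family|relatives) temporarily	staying with friends temporarily|staying with family temporarily|staying with relatives temporarily	false	curated extension
exposure	sleeping (outside|outdoors|in the open|in the cold)	sleeping outside|sleeping outdoors|sleeping in the open|sleeping in the cold	false	curated extension
exposure	expos(ure|ed) to the (elements|cold|heat)	exposure to the elements|exposure to the cold|exposure to the heat|exposed to the elements|exposed to the cold	false	curated extension
exposure	cold exposure	cold exposure	false	curated extension
exposure	environmental exposure	environmental exposure	false	curated extension
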