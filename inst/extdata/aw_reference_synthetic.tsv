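canonical_name	synonyms	minima	ermi_group
Stachybotrys chartarum	Stachybotrys atra	0.93;0.95	1
Chaetomium globosum		0.88;0.92	1
Trichoderma viride		0.92	1
Aureobasidium pullulans	Pullularia pullulans	0.90	1
Aspergillus flavus		0.80;0.84	1
Aspergillus fumigatus		0.85	1
Aspergillus niger		0.84	1
Aspergillus sydowii		0.81	1
Paecilomyces variotii	Byssochlamys spectabilis	0.84	1
Penicillium brevicompactum		0.82	1
Penicillium crustosum		0.83	1
Cladosporium sphaerospermum		0.82	1
Aspergillus penicillioides		0.68;0.78	1
Aspergillus restrictus		0.71;0.75	1
Aspergillus unguis		0.75	1
Aspergillus versicolor		0.74;0.80	1
Aspergillus ochraceus		0.79	1
Aspergillus amstelodami	Eurotium amstelodami	0.70	1
Aspergillus chevalieri	Eurotium chevalieri	0.71	1
Aspergillus montevidensis	Eurotium montevidense	0.72	1
Aspergillus pseudoglaucus	Eurotium repens	0.72	1
Wallemia sebi		0.69;0.75	1
Penicillium corylophilum		0.79	1
Penicillium spinulosum		0.79	1
Cladosporium halotolerans		0.78	1
Scopulariopsis brevicaulis		0.79	1
Aspergillus sclerotiorum			1
Aspergillus calidoustus			1
Aspergillus hiratsukae			1
Aspergillus creber			1
Aspergillus jensenii			1
Aspergillus protuberus			1
Aspergillus puulaauensis			1
Penicillium purpurogenum			1
Penicillium variabile			1
Penicillium fellutanum			1
Scopulariopsis chartarum			1
Scopulariopsis fusca			1
Scopulariopsis candida			1
Stachybotrys chlorohalonata			1
Memnoniella echinata			1
Trichoderma atroviride			1
Trichoderma koningii			1
Rhodotorula mucilaginosa	Rhodotorula rubra	0.92	none
Fusarium oxysporum		0.90	none
Fusarium solani		0.90	none
Fusarium culmorum		0.89;0.93	none
Mucor racemosus		0.93	2
Mucor plumbeus		0.92	none
Rhizopus stolonifer	Rhizopus nigricans	0.93	2
Botrytis cinerea		0.93	none
Phoma herbarum		0.92	none
Ulocladium chartarum		0.90	none
Acremonium strictum	Sarocladium strictum	0.90	2
Chaetomium elatum		0.91	none
Trichoderma harzianum		0.91	none
Candida tropicalis		0.92	none
Aspergillus ruber	Eurotium rubrum	0.70;0.72	none
Aspergillus glaucus	Eurotium herbariorum	0.70	none
Aspergillus halophilicus		0.68	none
Aspergillus vitricola		0.70	none
Aspergillus cristatus	Eurotium cristatum	0.71	none
Aspergillus caesiellus		0.73	none
Aspergillus conicus		0.73	none
Wallemia muriae		0.69	none
Wallemia ichthyophaga		0.66	none
Xeromyces bisporus		0.61	none
Penicillium implicatum		0.78	none
Talaromyces rugulosus	Penicillium rugulosum	0.79	none
Bettsia alvei		0.66	none
Chrysosporium fastidium		0.69	none
Chrysosporium xerophilum		0.71	none
Aspergillus tamarii		0.80	none
Aspergillus terreus		0.83	none
Aspergillus candidus		0.80	none
Aspergillus clavatus		0.88	none
Penicillium citrinum		0.80;0.82	none
Penicillium chrysogenum	Penicillium notatum	0.82	2
Penicillium expansum		0.83	none
Penicillium digitatum		0.87	none
Penicillium glabrum	Penicillium frequentans	0.82	none
Penicillium roqueforti		0.83	none
Penicillium commune		0.83	none
Penicillium palitans		0.82	none
Penicillium olsonii		0.84	none
Penicillium solitum		0.83	none
Penicillium aurantiogriseum		0.81	none
Penicillium viridicatum		0.81	none
Penicillium rubens		0.82	none
Cladosporium cladosporioides		0.86	2
Cladosporium herbarum		0.85	2
Cladosporium macrocarpum		0.86	none
Cladosporium oxysporum		0.85	none
Cladosporium ramotenellum		0.84	none
Cladosporium allicinum		0.85	none
Cladosporium delicatulum		0.85	none
Cladosporium limoniforme		0.85	none
Cladosporium perangustum		0.86	none
Cladosporium pseudocladosporioides		0.85	none
Cladosporium subuliforme		0.86	none
Cladosporium tenuissimum		0.85	none
Cladosporium westerdijkiae		0.85	none
Epicoccum nigrum	Epicoccum purpurascens	0.86	2
Alternaria alternata	Alternaria tenuis	0.85	2
Alternaria tenuissima		0.85	none
Aureobasidium melanogenum		0.86	none
Curvularia lunata		0.87	none
Curvularia inaequalis		0.87	none
Epicoccum brasiliense		0.86	none
Exophiala dermatitidis		0.85	none
Knufia epidermidis		0.86	none
Toxicocladosporium irritans		0.84	none
Cyberlindnera jadinii	Candida utilis	0.87	none
Debaryomyces hansenii		0.83	none
Hortaea werneckii		0.85	none
Phialophora verrucosa		0.86	none
Talaromyces wortmannii		0.84	none
Talaromyces funiculosus	Penicillium funiculosum	0.84	none
Paecilomyces niveus		0.84	none
Microascus trigonosporus		0.85	none
Syncephalastrum racemosum		0.84	none
Sarocladium kiliense		0.86	none
Geotrichum candidum		0.88	none
Naganishia albida	Cryptococcus albidus	0.86	none
Naganishia diffluens	Cryptococcus diffluens	0.86	none
Mucor amphibiorum			2
Rhizopus azygosporus			2
Acremonium persicinum			2
Alternaria infectoria			2
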