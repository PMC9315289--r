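## Synthetic reconstruction of the adherence decisional circuit:
## 18 behavioral/demographic factors, 43 signed regulatory interactions.
## The published figure of the study network is not machine-readable, so
## this edge list was transcribed from the causal relations described in
## the accompanying text; each edge row is annotated with its rationale.
## Node columns: name, kind (dynamic|input), n_levels, targetable (0|1).
## Edge columns: source, target, sign (+ activating, - inhibiting).
# adherence et_adherence
# nodes
age	input	3	0
education	input	3	0
income	input	3	0
tumor_stage	input	3	0
comorbidity	dynamic	3	0
side_effects	dynamic	3	0
qol	dynamic	3	1
general_anxiety	dynamic	3	1
recurrence_worry	dynamic	3	1
risk_perception	dynamic	3	0
numeracy	dynamic	3	0
health_literacy	dynamic	3	1
cost_worry	dynamic	3	1
routines	dynamic	3	1
coping_deficit	dynamic	3	1
provider_satisfaction	dynamic	3	0
trust_physician	dynamic	3	1
et_adherence	dynamic	3	0
# edges
## higher age lowers perceived recurrence risk
age	risk_perception	-
## education improves understanding of recurrence risk
education	risk_perception	+
## lower disease stage relates to lower perceived risk
tumor_stage	risk_perception	+
## education builds health literacy
education	health_literacy	+
## education builds numeracy
education	numeracy	+
## higher income relieves out-of-pocket cost worry
income	cost_worry	-
## age accumulates comorbid conditions
age	comorbidity	+
## understanding the rationale for treatment raises perceived risk
health_literacy	risk_perception	+
## numeric risk comprehension raises perceived risk
numeracy	risk_perception	+
## health literacy supports automated refill and pill routines
health_literacy	routines	+
## health literacy reduces unmanaged side-effect burden
health_literacy	coping_deficit	-
## comorbidities erode quality of life
comorbidity	qol	-
## complex comedication schedules disrupt routines
comorbidity	routines	-
## comorbid illness compounds treatment side effects
comorbidity	side_effects	+
## endocrine side effects erode quality of life
side_effects	qol	-
## unmanaged side effects reveal coping deficits
side_effects	coping_deficit	+
## symptom burden feeds general anxiety
side_effects	general_anxiety	+
## coping deficits erode quality of life
coping_deficit	qol	-
## coping deficits feed general anxiety
coping_deficit	general_anxiety	+
## anxiety erodes quality of life
general_anxiety	qol	-
## anxiety amplifies worry about recurrence
general_anxiety	recurrence_worry	+
## recurrence worry feeds back into general anxiety
recurrence_worry	general_anxiety	+
## worry raises perceived recurrence risk
recurrence_worry	risk_perception	+
## fear of recurrence motivates staying on treatment
recurrence_worry	et_adherence	+
## perceived risk motivates staying on treatment
risk_perception	et_adherence	+
## perceived risk sustains worry
risk_perception	recurrence_worry	+
## acceptable quality of life supports persistence
qol	et_adherence	+
## good quality of life dampens anxiety
qol	general_anxiety	-
## trust in the physician supports persistence
trust_physician	et_adherence	+
## trust colors satisfaction with the provider
trust_physician	provider_satisfaction	+
## satisfying provider interactions build trust
provider_satisfaction	trust_physician	+
## provider help managing side effects lowers their burden
provider_satisfaction	side_effects	-
## perceived provider helpfulness buffers quality of life
provider_satisfaction	qol	+
## trusted guidance closes coping deficits
trust_physician	coping_deficit	-
## financial burden pushes toward discontinuation
cost_worry	et_adherence	-
## financial strain feeds anxiety
cost_worry	general_anxiety	+
## consistent pill-taking routines sustain adherence
routines	et_adherence	+
## taking the pill daily produces side effects
et_adherence	side_effects	+
## staying on treatment quells worry about recurrence
et_adherence	recurrence_worry	-
## daily adherence entrenches behavioral routines
et_adherence	routines	+
## anxiety breaks down daily routines
general_anxiety	routines	-
## income buffers quality of life
income	qol	+
## older age heightens side-effect burden
age	side_effects	+
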