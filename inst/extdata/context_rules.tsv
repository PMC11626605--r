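# ConText-style assertion trigger rules
# version: 1.0
# columns: rule_id, trigger, dimension, value, direction, max_scope_tokens, enabled
# value "none" marks pseudo-triggers that only block real triggers;
# dimension "termination" rows end any scope early. Disabled rows are the
# pruned test-result negations: housing issues are not items for which
# patients test positive or negative, so these must never fire (kept for
# audit).
rule_id	trigger	dimension	value	direction	max_scope_tokens	enabled
neg_no	no	negation	negated	forward		true
neg_not	not	negation	negated	forward		true
neg_denies	denies	negation	negated	forward		true
neg_denied	denied	negation	negated	forward		true
neg_without	without	negation	negated	forward		true
neg_no_evidence_of	no evidence of	negation	negated	forward		true
neg_no_signs_of	no signs? of	negation	negated	forward		true
neg_negative_for	negative for	negation	negated	forward		true
neg_never	never	negation	negated	forward		true
neg_ruled_out	ruled out	negation	negated	backward		true
neg_unlikely	unlikely	negation	negated	backward		true
pseudo_no_increase	no (increase|change|further)	negation	none	forward		true
pseudo_not_only	not only	negation	none	forward		true
pseudo_no_doubt	no doubt	negation	none	forward		true
did_not_demonstrate	did not demonstrate	negation	negated	forward		false
neg_tested_negative	tested negative for	negation	negated	forward		false
neg_did_not_reveal	did not reveal	negation	negated	forward		false
hist_history_of	history of	temporality	historical	forward		true
hist_hx_of	hx of	temporality	historical	forward		true
hist_ho	h/o	temporality	historical	forward		true
hist_past_history	past history	temporality	historical	forward		true
hist_previously	previously	temporality	historical	forward		true
hist_in_the_past	in the past	temporality	historical	backward		true
exp_brother	brother	experiencer	other_experiencer	forward		true
exp_sister	sister	experiencer	other_experiencer	forward		true
exp_mother	mother	experiencer	other_experiencer	forward		true
exp_father	father	experiencer	other_experiencer	forward		true
exp_husband	husband	experiencer	other_experiencer	forward		true
exp_wife	wife	experiencer	other_experiencer	forward		true
exp_son	son	experiencer	other_experiencer	forward		true
exp_daughter	daughter	experiencer	other_experiencer	forward		true
exp_family_member	family member	experiencer	other_experiencer	forward		true
exp_neighbor	neighbor	experiencer	other_experiencer	forward		true
term_but	but	termination	terminate	bidirectional		true
term_however	however	termination	terminate	bidirectional		true
term_except	except	termination	terminate	bidirectional		true
term_although	(al)?though	termination	terminate	bidirectional		true
term_aside_from	aside from	termination	terminate	bidirectional		true
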