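# Causal keyword / phrase lexicon (45 entries): words and phrases that signal
# a drug causing a side-effect in patient forum messages.
# One entry per line, case-insensitive, up to 5 tokens.
after having
after stopping
because of this
caused by
cause of
developed
due to
effects from
effects of
ever since
experienced
experiencing
feeling
feel like
felt like
found out
found that
had a problem
have been getting
have been having
have noticed
have started
i am having
i am starting
i now have
made me feel
makes me feel
now i have
problems with
problem with
reaction to
result of
side affects
side effect
side effects
since i got
since i stopped
since then
started getting
started having
started noticing
started taking
started to
starting to feel
was causing
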