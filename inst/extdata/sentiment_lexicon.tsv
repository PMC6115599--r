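# Seed sentiment lexicon: adjective <TAB> polarity.
# Replaceable via read_lexicon() with any larger dictionary.
great	positive
good	positive
nice	positive
sweet	positive
strong	positive
reasonable	positive
perfect	positive
smooth	positive
excellent	positive
amazing	positive
awesome	positive
delicious	positive
tasty	positive
wonderful	positive
fantastic	positive
lovely	positive
pleasant	positive
fresh	positive
crisp	positive
clean	positive
rich	positive
deep	positive
solid	positive
superb	positive
outstanding	positive
impressive	positive
satisfying	positive
enjoyable	positive
balanced	positive
authentic	positive
accurate	positive
fair	positive
affordable	positive
inexpensive	positive
juicy	positive
bold	positive
robust	positive
dense	positive
thick	positive
huge	positive
big	positive
massive	positive
generous	positive
decent	positive
fine	positive
mellow	positive
gentle	positive
classic	positive
favorite	positive
incredible	positive
remarkable	positive
delightful	positive
refreshing	positive
vibrant	positive
intense	positive
premium	positive
natural	positive
pure	positive
consistent	positive
reliable	positive
brilliant	positive
beautiful	positive
yummy	positive
divine	positive
heavenly	positive
bad	negative
terrible	negative
harsh	negative
weak	negative
sour	negative
bitter	negative
steep	negative
expensive	negative
crazy	negative
nonexistent	negative
unpleasant	negative
poor	negative
soapy	negative
odd	negative
strange	negative
awful	negative
nasty	negative
horrible	negative
disgusting	negative
gross	negative
bland	negative
stale	negative
burnt	negative
chemical	negative
artificial	negative
fake	negative
muted	negative
faint	negative
thin	negative
watery	negative
overpriced	negative
costly	negative
cheap	negative
weird	negative
dull	negative
flat	negative
rough	negative
dry	negative
disappointing	negative
mediocre	negative
inconsistent	negative
overwhelming	negative
overpowering	negative
sickening	negative
cloying	negative
acrid	negative
metallic	negative
plastic	negative
perfumy	negative
medicinal	negative
stinging	negative
scratchy	negative
painful	negative
annoying	negative
useless	negative
worthless	negative
pathetic	negative
lousy	negative
subpar	negative
inferior	negative
unbearable	negative
revolting	negative
rancid	negative
foul	negative
funky	negative
musty	negative
skunky	negative
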